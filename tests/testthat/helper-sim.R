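# Small acquisition settings for unit tests: full acquisition geometry but
# far fewer frames, so each simulated field costs well under a second.
small_params <- function(seed = 1, ...) {
  args <- list(n_frames_signal = 400, n_frames_dapi = 150, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# a single noiseless PSF frame with a constant offset
psf_frame <- function(h = 21, w = 21, x_px = 10.5, y_px = 10.5,
                      photons = 5000, sigma_px = 1.3, offset = 0) {
  em <- data.frame(x_nm = x_px * 100, y_nm = y_px * 100, photons = photons)
  synthesize_frame(em, psf_sigma_nm = sigma_px * 100, pixel_size_nm = 100,
                   background_field = matrix(offset, h, w), poisson = FALSE)
}
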