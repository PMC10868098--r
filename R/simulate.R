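#' Simulation parameters for a synthetic FISH acquisition
#'
#' Describes one imaged field of a dual-probe HER2/CEP17 FISH slide as seen
#' by a single-molecule localization microscope: stochastically blinking
#' emitters grouped into FISH loci inside elliptical nuclei, on top of a
#' smooth autofluorescence background with shot and read noise. Acquisition
#' defaults follow the imaging protocol the pipeline targets: 5000 frames
#' per signal channel, 1000 DAPI frames, 30 ms exposure, a diffraction-
#' limited PSF of 130 nm sigma. The camera pitch (100 nm/px, consistent
#' with a 100x/1.4 objective) and the photophysics/background values are
#' engineering defaults chosen at desk scale; see the methods vignette.
#'
#' @param field_px field edge length in pixels (`>= 32`).
#' @param pixel_size_nm camera pixel pitch (nm).
#' @param n_frames_signal frames per HER2/CEP17 channel.
#' @param n_frames_dapi frames for the DAPI channel.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_px range `c(min, max)` of ellipse semi-axes (px).
#' @param her2_per_nucleus,cep17_per_nucleus signals per nucleus; scalar or
#'   length-`n_nuclei` vector.
#' @param emitters_per_signal fluorophore copies per FISH locus.
#' @param signal_extent_nm spatial spread of one locus (nm).
#' @param p_on per-frame blink probability, in (0, 1).
#' @param mean_photons mean photons per on-event (Poisson).
#' @param psf_sigma_nm Gaussian PSF sigma (nm).
#' @param background_amplitude,background_corr_len_px,background_offset
#'   autofluorescence model: smooth Gaussian random field of this marginal
#'   SD and correlation length added to a constant offset, clipped at 0.
#' @param read_noise_sd Gaussian read noise SD (ADU).
#' @param cluster_fraction fraction of nuclei given one unresolvable
#'   cluster locus of `cluster_signals` co-located HER2 signals (exercises
#'   the "more than four signals" ambiguity rule).
#' @param cluster_signals signals per cluster locus (`> 4`).
#' @param min_signal_sep_nm minimum within-channel spacing between loci.
#' @param dapi_intensity mean DAPI fluorescence per nucleus pixel (ADU).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(field_px = 64, pixel_size_nm = 100,
                       n_frames_signal = 5000, n_frames_dapi = 1000,
                       n_nuclei = 5, nucleus_radius_px = c(7, 10),
                       her2_per_nucleus = 2, cep17_per_nucleus = 2,
                       emitters_per_signal = 8, signal_extent_nm = 80,
                       p_on = 0.005, mean_photons = 1500,
                       psf_sigma_nm = 130, background_amplitude = 20,
                       background_corr_len_px = 8, background_offset = 100,
                       read_noise_sd = 3, cluster_fraction = 0,
                       cluster_signals = 6, min_signal_sep_nm = 500,
                       dapi_intensity = 60, seed = 1) {
  p <- as.list(environment())
  if (field_px < 32) stop_fq("fq_param", "'field_px' must be >= 32")
  if (p_on <= 0 || p_on >= 1) stop_fq("fq_param", "'p_on' must be in (0,1)")
  if (psf_sigma_nm <= 0 || pixel_size_nm <= 0)
    stop_fq("fq_param", "PSF sigma and pixel size must be > 0")
  counts <- c(n_frames_signal, n_frames_dapi, n_nuclei, her2_per_nucleus,
              cep17_per_nucleus, emitters_per_signal, cluster_signals)
  if (any(counts < 0)) stop_fq("fq_param", "counts must be >= 0")
  if (cluster_fraction < 0 || cluster_fraction > 1)
    stop_fq("fq_param", "'cluster_fraction' must be in [0,1]")
  if (length(nucleus_radius_px) == 1L)
    p$nucleus_radius_px <- rep(nucleus_radius_px, 2L)
  structure(p, class = "sim_params")
}

#' Smooth autofluorescence background field
#'
#' Generates the clean (noise-free) autofluorescence component of a frame:
#' a stationary Gaussian random field with unit marginal variance and
#' Gaussian autocorrelation of length `corr_len_px` (built by circular
#' convolution of white noise, so the marginal variance is exact), scaled
#' by `amplitude`, shifted by `offset` and clipped at zero. With
#' `amplitude = 0` the result is the constant `offset`.
#'
#' @param field_px image edge length (px).
#' @param amplitude marginal SD of the smooth component (ADU), `>= 0`.
#' @param corr_len_px autocorrelation length (px), `>= 1`.
#' @param offset constant background level (ADU).
#' @param seed optional RNG seed (set for a deterministic field).
#' @return `field_px x field_px` non-negative matrix.
#' @export
make_background_field <- function(field_px, amplitude, corr_len_px, offset,
                                  seed = NULL) {
  if (field_px <= 0) stop_fq("fq_param", "'field_px' must be positive")
  if (amplitude < 0 || corr_len_px < 1)
    stop_fq("fq_param", "need amplitude >= 0 and corr_len_px >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0)
    return(matrix(pmax(0, offset), field_px, field_px))
  n <- field_px
  # circulant separable Gaussian smoothing kernel; sd chosen so the output
  # autocorrelation length (kernel self-convolution) is corr_len_px
  s <- corr_len_px / sqrt(2)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    dd <- abs(i - j)
    pmin(dd, n - dd)
  })
  K <- exp(-d^2 / (2 * s^2))
  w <- matrix(rnorm(n * n), n, n)
  b <- K %*% w %*% t(K)
  z <- b / sum(K[1, ]^2)               # unit marginal variance, exactly
  pmax(offset + amplitude * z, 0)
}

#' Per-frame photon trace of one blinking emitter
#'
#' Photoswitching is modeled as i.i.d. Bernoulli blinking: in each frame
#' the emitter is "on" with probability `p_on`, independently of its
#' history; an on-frame emits `Poisson(mean_photons)` photons, an
#' off-frame emits none.
#'
#' @param n_frames trace length (`>= 1`).
#' @param p_on per-frame on-probability, strictly inside (0, 1).
#' @param mean_photons mean photons per on-event.
#' @param seed optional RNG seed.
#' @return Integer vector of per-frame photon counts.
#' @export
simulate_blinking_trace <- function(n_frames, p_on = 0.005,
                                    mean_photons = 1500, seed = NULL) {
  if (n_frames < 1) stop_fq("fq_param", "'n_frames' must be >= 1")
  if (p_on <= 0 || p_on >= 1) stop_fq("fq_param", "'p_on' must be in (0,1)")
  if (!is.null(seed)) set.seed(seed)
  trace <- integer(n_frames)
  on <- runif(n_frames) < p_on
  trace[on] <- rpois(sum(on), mean_photons)
  trace
}

#' Render one camera frame from active emitters
#'
#' Forward model of the camera: each active emitter contributes its photon
#' count spread as a 2-D Gaussian PSF *integrated over pixels* (so the
#' noiseless pixel sum equals the emitted photons up to edge truncation),
#' added to the clean background field; shot noise is Poisson per pixel and
#' read noise additive Gaussian, after which the frame is rounded and
#' clipped to the 16-bit range.
#'
#' @param emitters `data.frame` with columns `x_nm`, `y_nm`, `photons`
#'   (may be empty or `NULL` for a background-only frame).
#' @param psf_sigma_nm PSF sigma (nm).
#' @param pixel_size_nm pixel pitch (nm).
#' @param background_field background matrix (defines the frame shape).
#' @param read_noise_sd Gaussian read noise SD (ADU); 0 disables it.
#' @param poisson if `FALSE`, return the noiseless expected frame
#'   (continuous values, no rounding).
#' @param seed optional RNG seed.
#' @return Numeric matrix of the same shape as `background_field`.
#' @export
synthesize_frame <- function(emitters, psf_sigma_nm = 130,
                             pixel_size_nm = 100, background_field,
                             read_noise_sd = 0, poisson = TRUE,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(background_field); w <- ncol(background_field)
  if (is.null(emitters) || nrow(emitters) == 0L) {
    expected <- background_field + 0
  } else {
    if (any(emitters$photons < 0))
      stop_fq("fq_param", "photon counts must be >= 0")
    x_px <- emitters$x_nm / pixel_size_nm
    y_px <- emitters$y_nm / pixel_size_nm
    if (any(x_px < 0 | x_px > w | y_px < 0 | y_px > h))
      stop_fq("fq_range", "emitter outside the field")
    expected <- background_field +
      cpp_expected_frame(h, w, x_px, y_px, emitters$photons,
                         psf_sigma_nm / pixel_size_nm)
  }
  if (!poisson && read_noise_sd == 0) return(expected)
  frame <- if (poisson) {
    matrix(rpois(h * w, as.vector(expected)), h, w)
  } else expected
  if (read_noise_sd > 0)
    frame <- frame + matrix(rnorm(h * w, 0, read_noise_sd), h, w)
  pmin(pmax(round(frame), 0), 65535)
}

# sample a point uniformly inside the ellipse (cx, cy, a, b, theta) shrunk
# by `shrink`; coordinates in px
sample_in_ellipse <- function(cx, cy, a, b, theta, shrink = 0.75) {
  r <- sqrt(runif(1))
  phi <- runif(1, 0, 2 * pi)
  u <- r * cos(phi) * a * shrink
  v <- r * sin(phi) * b * shrink
  c(cx + u * cos(theta) - v * sin(theta),
    cy + u * sin(theta) + v * cos(theta))
}

ellipse_mask <- function(field_px, cx, cy, a, b, theta) {
  xs <- seq_len(field_px) - 0.5
  X <- matrix(xs, field_px, field_px, byrow = TRUE)
  Y <- matrix(xs, field_px, field_px)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

simulate_channel_stack <- function(emitters_px, params, n_frames, bg) {
  ne <- nrow(emitters_px)
  events <- NULL
  if (ne > 0) {
    ev <- vector("list", ne)
    for (k in seq_len(ne)) {
      trace <- simulate_blinking_trace(n_frames, params$p_on,
                                       params$mean_photons)
      on <- which(trace > 0)
      if (length(on))
        ev[[k]] <- data.frame(frame = on - 1L, x_px = emitters_px$x_px[k],
                              y_px = emitters_px$y_px[k],
                              photons = trace[on])
    }
    events <- do.call(rbind, ev)
  }
  if (is.null(events))
    events <- data.frame(frame = integer(0), x_px = numeric(0),
                         y_px = numeric(0), photons = numeric(0))
  events <- events[order(events$frame), , drop = FALSE]
  data <- cpp_synth_stack(bg, as.integer(events$frame), events$x_px,
                          events$y_px, events$photons,
                          params$psf_sigma_nm / params$pixel_size_nm,
                          as.integer(n_frames), params$read_noise_sd)
  list(data = data, events = events)
}

#' Simulate a full dual-probe FISH field with ground truth
#'
#' Places non-overlapping elliptical nuclei, draws HER2 and CEP17 loci
#' inside them (optionally adding one unresolvable cluster locus of
#' `cluster_signals` co-located HER2 signals to a `cluster_fraction` of
#' nuclei), spreads `emitters_per_signal` fluorophores around every locus,
#' simulates Bernoulli blinking over the acquisition and renders the three
#' channel stacks (HER2, CEP17, DAPI). Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `sim_field` with elements `her2`, `cep17`,
#'   `dapi` ([fish_stack()]s), `conventional` (one conventional-exposure
#'   snapshot per signal channel: a single frame with every fluorophore
#'   emitting, i.e. the widefield image a routine fluorescence microscope
#'   would capture before photoswitching) and `truth`, a list holding the
#'   nucleus table and label mask, the signal and emitter tables (nm
#'   coordinates, cluster flags), per-nucleus true counts `H`/`C`, the
#'   clean background fields and the per-frame emission events of each
#'   channel.
#' @export
simulate_field <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$field_px
  p <- params$pixel_size_nm
  bg_her2 <- make_background_field(n, params$background_amplitude,
                                   params$background_corr_len_px,
                                   params$background_offset)
  bg_cep17 <- make_background_field(n, params$background_amplitude,
                                    params$background_corr_len_px,
                                    params$background_offset)
  bg_dapi <- make_background_field(n, params$background_amplitude / 2,
                                   params$background_corr_len_px,
                                   params$background_offset / 2)

  # --- nuclei: random non-overlapping ellipses -----------------------------
  rr <- params$nucleus_radius_px
  empty_nuclei <- data.frame(id = integer(0), cx = numeric(0),
                             cy = numeric(0), a = numeric(0), b = numeric(0),
                             theta = numeric(0))
  nuclei <- empty_nuclei
  # greedy placement can paint itself into a corner: restart when stuck
  for (restart in seq_len(25L)) {
    nuclei <- empty_nuclei
    attempts <- 0L
    while (nrow(nuclei) < params$n_nuclei && attempts < 200L) {
      attempts <- attempts + 1L
      a <- runif(1, rr[1], rr[2]); b <- runif(1, rr[1], rr[2])
      rmax <- max(a, b)
      cx <- runif(1, rmax + 1, n - rmax - 1)
      cy <- runif(1, rmax + 1, n - rmax - 1)
      if (nrow(nuclei) > 0) {
        d <- sqrt((nuclei$cx - cx)^2 + (nuclei$cy - cy)^2)
        if (any(d < pmax(nuclei$a, nuclei$b) + rmax + 1)) next
      }
      nuclei <- rbind(nuclei, data.frame(id = nrow(nuclei) + 1L, cx = cx,
                                         cy = cy, a = a, b = b,
                                         theta = runif(1, 0, pi)))
    }
    if (nrow(nuclei) == params$n_nuclei) break
  }
  if (nrow(nuclei) < params$n_nuclei)
    stop_fq("fq_placement", "could not place ", params$n_nuclei,
            " non-overlapping nuclei in a ", n, " px field")
  mask <- matrix(0L, n, n)
  for (k in seq_len(nrow(nuclei)))
    mask[ellipse_mask(n, nuclei$cx[k], nuclei$cy[k], nuclei$a[k],
                      nuclei$b[k], nuclei$theta[k])] <- nuclei$id[k]

  n_cluster <- round(params$cluster_fraction * params$n_nuclei)
  cluster_ids <- if (n_cluster > 0)
    sample(nuclei$id, n_cluster) else integer(0)

  per_nuc <- function(x) if (length(x) == 1L) rep(x, params$n_nuclei) else x
  n_her2 <- per_nuc(params$her2_per_nucleus)
  n_cep17 <- per_nuc(params$cep17_per_nucleus)

  # --- loci and emitters ---------------------------------------------------
  signals <- list()
  place_signals <- function(nuc, n_sig, channel, existing_px) {
    placed <- existing_px
    out <- NULL
    min_sep_px <- params$min_signal_sep_nm / p
    for (s in seq_len(n_sig)) {
      pos <- NULL
      for (try in seq_len(500L)) {
        cand <- sample_in_ellipse(nuc$cx, nuc$cy, nuc$a, nuc$b, nuc$theta)
        if (is.null(placed) || nrow(placed) == 0L ||
            all(sqrt((placed[, 1] - cand[1])^2 +
                     (placed[, 2] - cand[2])^2) >= min_sep_px)) {
          pos <- cand
          break
        }
      }
      if (is.null(pos))
        pos <- sample_in_ellipse(nuc$cx, nuc$cy, nuc$a, nuc$b, nuc$theta)
      placed <- rbind(placed, matrix(pos, 1))
      out <- rbind(out, data.frame(channel = channel, nucleus_id = nuc$id,
                                   x_nm = pos[1] * p, y_nm = pos[2] * p,
                                   is_cluster = FALSE))
    }
    list(signals = out, placed = placed)
  }
  for (k in seq_len(nrow(nuclei))) {
    nuc <- nuclei[k, ]
    placed_h <- matrix(numeric(0), 0, 2)
    if (n_her2[k] > 0) {
      res <- place_signals(nuc, n_her2[k], "HER2", placed_h)
      signals[[length(signals) + 1L]] <- res$signals
      placed_h <- res$placed
    }
    if (nuc$id %in% cluster_ids && params$cluster_signals > 0) {
      # one unresolvable cluster locus: > 4 signals within signal_extent_nm
      res <- place_signals(nuc, 1L, "HER2", placed_h)
      ctr <- c(res$signals$x_nm, res$signals$y_nm)
      rad <- sqrt(runif(params$cluster_signals)) * params$signal_extent_nm / 2
      ang <- runif(params$cluster_signals, 0, 2 * pi)
      signals[[length(signals) + 1L]] <-
        data.frame(channel = "HER2", nucleus_id = nuc$id,
                   x_nm = ctr[1] + rad * cos(ang),
                   y_nm = ctr[2] + rad * sin(ang), is_cluster = TRUE)
    }
    if (n_cep17[k] > 0) {
      res <- place_signals(nuc, n_cep17[k], "CEP17", matrix(numeric(0), 0, 2))
      signals[[length(signals) + 1L]] <- res$signals
    }
  }
  signals <- if (length(signals)) do.call(rbind, signals) else
    data.frame(channel = character(0), nucleus_id = integer(0),
               x_nm = numeric(0), y_nm = numeric(0), is_cluster = logical(0))
  rownames(signals) <- NULL
  if (nrow(signals)) signals$id <- seq_len(nrow(signals))

  emitters <- NULL
  if (nrow(signals) > 0) {
    epp <- params$emitters_per_signal
    # ~95% of a locus' fluorophores fall within a signal_extent_nm circle
    sd_nm <- params$signal_extent_nm / 4
    ex <- rep(signals$x_nm, each = epp) + rnorm(nrow(signals) * epp, 0, sd_nm)
    ey <- rep(signals$y_nm, each = epp) + rnorm(nrow(signals) * epp, 0, sd_nm)
    emitters <- data.frame(signal_id = rep(signals$id, each = epp),
                           channel = rep(signals$channel, each = epp),
                           x_nm = pmin(pmax(ex, 0), n * p - 1e-9),
                           y_nm = pmin(pmax(ey, 0), n * p - 1e-9))
  } else {
    emitters <- data.frame(signal_id = integer(0), channel = character(0),
                           x_nm = numeric(0), y_nm = numeric(0))
  }

  # --- acquisition ---------------------------------------------------------
  ch_emitters <- function(ch) {
    e <- emitters[emitters$channel == ch, , drop = FALSE]
    data.frame(x_px = e$x_nm / p, y_px = e$y_nm / p)
  }
  her2 <- simulate_channel_stack(ch_emitters("HER2"), params,
                                 params$n_frames_signal, bg_her2)
  cep17 <- simulate_channel_stack(ch_emitters("CEP17"), params,
                                  params$n_frames_signal, bg_cep17)
  # conventional-exposure snapshots: one frame per signal channel with every
  # fluorophore emitting at once (widefield imaging before photoswitching)
  conv <- lapply(c(HER2 = "HER2", CEP17 = "CEP17"), function(ch) {
    e <- emitters[emitters$channel == ch, , drop = FALSE]
    e <- data.frame(x_nm = e$x_nm, y_nm = e$y_nm,
                    photons = if (nrow(e)) rpois(nrow(e), params$mean_photons)
                              else numeric(0))
    synthesize_frame(e, params$psf_sigma_nm, p,
                     if (ch == "HER2") bg_her2 else bg_cep17,
                     read_noise_sd = params$read_noise_sd)
  })
  psf_px <- params$psf_sigma_nm / p
  dapi_expected <- bg_dapi + params$dapi_intensity *
    gaussian_blur(1.0 * (mask > 0), psf_px)
  dapi <- simulate_channel_stack(data.frame(x_px = numeric(0),
                                            y_px = numeric(0)),
                                 params, params$n_frames_dapi, dapi_expected)

  per_nucleus <- data.frame(
    nucleus_id = nuclei$id,
    H = vapply(nuclei$id, function(i)
      sum(signals$channel == "HER2" & signals$nucleus_id == i), integer(1)),
    C = vapply(nuclei$id, function(i)
      sum(signals$channel == "CEP17" & signals$nucleus_id == i), integer(1)),
    has_cluster = nuclei$id %in% cluster_ids)

  truth <- list(
    nuclei = data.frame(id = nuclei$id, x_nm = nuclei$cx * p,
                        y_nm = nuclei$cy * p, a_px = nuclei$a,
                        b_px = nuclei$b, theta = nuclei$theta),
    nucleus_mask = mask,
    signals = signals,
    emitters = emitters,
    per_nucleus = per_nucleus,
    background = list(HER2 = bg_her2, CEP17 = bg_cep17, DAPI = bg_dapi,
                      dapi_expected = dapi_expected),
    events = list(HER2 = her2$events, CEP17 = cep17$events),
    params = params)

  meta <- list(simulated = TRUE, seed = params$seed)
  structure(list(
    her2 = fish_stack(her2$data, p, "HER2", metadata = meta),
    cep17 = fish_stack(cep17$data, p, "CEP17", metadata = meta),
    dapi = fish_stack(dapi$data, p, "DAPI", metadata = meta),
    conventional = conv,
    truth = truth), class = "sim_field")
}

# separable Gaussian blur with mirror padding (used for the DAPI forward
# model); kernel truncated at 4 sigma
gaussian_blur <- function(img, sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  mi <- function(q, nn) ifelse(q < 1, 2 - q, ifelse(q > nn, 2 * nn - q, q))
  pad_r <- mi(seq(1 - r, n + r), n)
  pad_c <- mi(seq(1 - r, m + r), m)
  padded <- img[pad_r, pad_c, drop = FALSE]
  tmp <- matrix(0, n, ncol(padded))
  for (d in -r:r) tmp <- tmp + k[d + r + 1] * padded[seq_len(n) + r + d, ]
  out <- matrix(0, n, m)
  for (d in -r:r) out <- out + k[d + r + 1] * tmp[, seq_len(m) + r + d]
  out
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf(paste0("<sim_field> %d nuclei, %d HER2 / %d CEP17 signals; ",
                     "%d+%d+%d frames of %d px\n"),
              nrow(x$truth$nuclei), sum(x$truth$signals$channel == "HER2"),
              sum(x$truth$signals$channel == "CEP17"),
              n_frames(x$her2), n_frames(x$cep17), n_frames(x$dapi),
              dim(x$her2$data)[1]))
  invisible(x)
}
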