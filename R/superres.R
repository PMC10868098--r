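#' Conventional-resolution (widefield) projection of a stack
#'
#' Pixel-wise reduction of all frames to one diffraction-limited image —
#' the "conventional resolution" view of an acquisition, without any
#' super-resolution processing.
#'
#' @param stack a [fish_stack()] (or 3-D array).
#' @param mode `"mean"` (default), `"sum"` or `"max"`.
#' @return 2-D numeric matrix.
#' @export
widefield_projection <- function(stack, mode = c("mean", "sum", "max")) {
  mode <- match.arg(mode)
  arr <- as_stack_array(stack)
  if (dim(arr)[3] < 1L) stop_fq("fq_param", "empty stack")
  switch(mode,
         mean = rowMeans(arr, dims = 2),
         sum = rowSums(arr, dims = 2),
         max = {
           out <- arr[, , 1]
           for (t in seq_len(dim(arr)[3])[-1]) out <- pmax(out, arr[, , t])
           out
         })
}

#' Detect candidate emitter peaks in one frame
#'
#' Local maxima under 8-connectivity (a pixel at least as bright as every
#' in-bounds neighbor) with intensity strictly above `tau`; maxima closer
#' than `min_separation_px` are merged into the brighter one.
#'
#' @param frame 2-D numeric matrix (typically denoised and/or
#'   background-subtracted).
#' @param tau intensity threshold.
#' @param min_separation_px merge radius in pixels (default 2).
#' @return `data.frame` with 1-based integer columns `row`, `col` and the
#'   peak `value`; zero rows when nothing is detected.
#' @export
detect_candidates <- function(frame, tau, min_separation_px = 2) {
  arr <- array(frame, dim = c(dim(frame), 1L))
  pk <- cpp_detect_stack(arr, as.numeric(tau), min_separation_px)
  data.frame(row = as.integer(pk[, 2]) + 1L, col = as.integer(pk[, 3]) + 1L,
             value = pk[, 4])
}

#' Sub-pixel Gaussian fit of a single candidate peak
#'
#' Least-squares fit of a symmetric 2-D Gaussian (amplitude, center,
#' sigma, constant offset) over a square window centered on the peak,
#' using a bounded Levenberg-Marquardt iteration seeded from the window
#' centroid. Fits that do not converge, leave the window, have
#' non-positive amplitude or a sigma outside `sigma_bounds` times the
#' expected PSF sigma are rejected.
#'
#' @param frame 2-D numeric matrix.
#' @param peak integer `c(row, col)` (1-based) peak pixel.
#' @param window_px odd window edge length (default 7).
#' @param pixel_size_nm pixel pitch (nm).
#' @param psf_sigma_nm expected PSF sigma, used as the fit seed and to
#'   bound the accepted sigma range.
#' @param gain camera gain in ADU per photon (photons =
#'   `amplitude * 2 * pi * sigma_px^2 / gain`).
#' @param sigma_bounds accepted fitted-sigma range as multiples of the
#'   expected PSF sigma.
#' @param max_iter,tol Levenberg-Marquardt iteration cap and relative
#'   cost tolerance.
#' @return One-row localization `data.frame` (see [as_localizations()]);
#'   a rejected fit yields a zero-row table whose `"rejection"` attribute
#'   names the reason.
#' @export
fit_gaussian_spot <- function(frame, peak, window_px = 7,
                              pixel_size_nm = 100, psf_sigma_nm = 130,
                              gain = 1, sigma_bounds = c(0.5, 4),
                              max_iter = 100, tol = 1e-8) {
  if (window_px %% 2 != 1) stop_fq("fq_param", "'window_px' must be odd")
  arr <- array(frame, dim = c(dim(frame), 1L))
  peaks <- matrix(c(0, peak[1] - 1, peak[2] - 1), 1)
  fit <- cpp_fit_spots(arr, peaks, as.integer((window_px - 1) / 2),
                       psf_sigma_nm / pixel_size_nm, sigma_bounds[1],
                       sigma_bounds[2], as.integer(max_iter), tol)
  tab <- fits_to_table(fit, pixel_size_nm, gain)
  if (nrow(tab) == 0L)
    attr(tab, "rejection") <- fit_status_labels()[fit[1, 7] + 1]
  tab
}

fit_status_labels <- function() {
  c("ok", "window_outside_frame", "no_convergence", "sigma_out_of_range",
    "non_positive_amplitude", "center_left_window")
}

fits_to_table <- function(fit, pixel_size_nm, gain) {
  ok <- fit[, 7] == 0
  f <- fit[ok, , drop = FALSE]
  sigma_px <- f[, 4]
  photons <- f[, 5] * 2 * pi * sigma_px^2 / gain
  tab <- data.frame(frame = as.integer(f[, 1]),
                    x_nm = f[, 2] * pixel_size_nm,
                    y_nm = f[, 3] * pixel_size_nm,
                    sigma_nm = sigma_px * pixel_size_nm,
                    photons = photons,
                    background = f[, 6],
                    uncertainty_nm = sigma_px * pixel_size_nm /
                      sqrt(pmax(photons, 1e-12)))
  drop <- photons <= 0
  tab <- tab[!drop, , drop = FALSE]
  rejections <- table(factor(fit_status_labels()[fit[, 7] + 1],
                             levels = fit_status_labels()))
  rejections["non_positive_amplitude"] <-
    rejections["non_positive_amplitude"] + sum(drop)
  rejections["ok"] <- rejections["ok"] - sum(drop)
  attr(tab, "rejections") <- rejections
  tab
}

#' Localize emitters across a whole stack
#'
#' Runs per-frame detection and sub-pixel Gaussian fitting over every
#' frame of the acquisition and concatenates the accepted fits into a
#' localization table. Optional preprocessing (blind-spot denoising,
#' per-frame rolling-ball background subtraction) is applied first; the
#' detection threshold is either a fixed `tau` or predicted per frame
#' from a [fit_threshold_model()] regression.
#'
#' @param stack a [fish_stack()].
#' @param tau fixed detection threshold (scalar or one per frame).
#' @param tau_model a `threshold_model` used to predict a per-frame
#'   threshold from frame mean and SD (ignored when `tau` is given).
#' @param denoise_model optional [train_blindspot()] model applied first.
#' @param preprocess background handling before thresholding:
#'   `"rolling_ball"` (default) subtracts a per-frame rolling-ball
#'   background of radius `subtract_radius_px` (4 px removes the
#'   spatially varying autofluorescence around diffraction-scale spots at
#'   a fraction of the cost of the classic 15-px radius used on
#'   projections); `"temporal_median"` subtracts the per-pixel median
#'   over a frame subsample (the autofluorescence is static while any
#'   emitter is on in only a small fraction of frames); `"none"` leaves
#'   frames untouched. Must match the preprocessing the `tau_model` was
#'   calibrated with.
#' @param subtract_radius_px rolling-ball radius for
#'   `preprocess = "rolling_ball"`.
#' @inheritParams fit_gaussian_spot
#' @param min_separation_px peak merge radius (px).
#' @return Localization `data.frame` (columns of [as_localizations()]),
#'   rows ordered by frame, with attribute `"rejections"` tabulating
#'   rejected fits by reason.
#' @export
localize_stack <- function(stack, tau = NULL, tau_model = NULL,
                           denoise_model = NULL,
                           preprocess = c("rolling_ball", "temporal_median",
                                          "none"),
                           subtract_radius_px = 4, psf_sigma_nm = 130,
                           window_px = 7, min_separation_px = 2, gain = 1,
                           sigma_bounds = c(0.5, 4), max_iter = 100,
                           tol = 1e-8) {
  stopifnot(inherits(stack, "fish_stack"))
  preprocess <- match.arg(preprocess)
  if (!is.null(denoise_model)) stack <- denoise_stack(denoise_model, stack)
  arr <- stack$data
  h <- dim(arr)[1]; w <- dim(arr)[2]; t <- dim(arr)[3]
  if (preprocess == "temporal_median") {
    bg <- temporal_median_background(arr)
    arr <- pmax(arr - as.vector(bg), 0)
  } else if (preprocess == "rolling_ball") {
    arr <- cpp_subtract_opening_stack(arr, as.integer(subtract_radius_px))
  }
  if (is.null(tau)) {
    if (is.null(tau_model))
      stop_fq("fq_param", "supply 'tau' or 'tau_model'")
    m <- matrix(arr, h * w, t)
    mu <- colMeans(m)
    s <- sqrt(pmax(colMeans(m^2) - mu^2, 0) * (h * w) / (h * w - 1))
    tau <- pmax(0, tau_model$coef_mean * mu + tau_model$coef_sd * s +
                  tau_model$intercept)
  }
  peaks <- cpp_detect_stack(arr, as.numeric(tau), min_separation_px)
  if (nrow(peaks) == 0L) {
    out <- as_localizations(NULL)
    attr(out, "rejections") <- table(factor(character(0),
                                            levels = fit_status_labels()))
    return(out)
  }
  fit <- cpp_fit_spots(arr, peaks[, 1:3, drop = FALSE],
                       as.integer((window_px - 1) / 2),
                       psf_sigma_nm / stack$pixel_size_nm, sigma_bounds[1],
                       sigma_bounds[2], as.integer(max_iter), tol)
  fits_to_table(fit, stack$pixel_size_nm, gain)
}

#' Quality-filter a localization table
#'
#' Standard post-fit filtering: localizations whose fitted sigma falls
#' outside `sigma_band` times the expected PSF sigma, or whose photon
#' count is below `min_photons_frac` of the table's median, are removed.
#' Single-emitter fits cluster tightly around the true PSF width and
#' photon budget; fits over residual background structure and fits of
#' two simultaneously active emitters in neighbouring loci (which land
#' between the loci with inflated widths) do not, and both would
#' otherwise bridge or fake signal clusters downstream.
#'
#' @param table localization `data.frame`.
#' @param psf_sigma_nm expected PSF sigma (nm).
#' @param sigma_band accepted fitted-sigma range, as multiples of
#'   `psf_sigma_nm`.
#' @param min_photons_frac minimum photons as a fraction of the median.
#' @return The filtered table (attribute `"n_filtered"` = rows removed).
#' @export
filter_localizations <- function(table, psf_sigma_nm = 130,
                                 sigma_band = c(0.75, 1.3),
                                 min_photons_frac = 0.25) {
  if (is.null(table) || nrow(table) == 0L) return(as_localizations(table))
  keep <- table$sigma_nm >= sigma_band[1] * psf_sigma_nm &
    table$sigma_nm <= sigma_band[2] * psf_sigma_nm &
    table$photons >= min_photons_frac * median(table$photons)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Per-pixel temporal median background of a stack
#'
#' Estimates the static background of a blinking acquisition as the
#' per-pixel median over up to `max_frames` evenly spaced frames;
#' emitters are on in too small a fraction of frames to move the median.
#'
#' @param arr `H x W x T` array (or [fish_stack()]).
#' @param max_frames frame subsample size.
#' @return `H x W` background matrix.
#' @export
temporal_median_background <- function(arr, max_frames = 201) {
  arr <- as_stack_array(arr)
  t <- dim(arr)[3]
  idx <- if (t <= max_frames) seq_len(t)
         else unique(round(seq(1, t, length.out = max_frames)))
  m <- matrix(arr[, , idx], dim(arr)[1] * dim(arr)[2], length(idx))
  matrix(apply(m, 1, median), dim(arr)[1], dim(arr)[2])
}

#' Render a super-resolution image from localizations
#'
#' `histogram` mode bins localization coordinates on a grid of
#' `render_px_nm` pixels (the image sum equals the number of
#' localizations exactly); `gaussian` mode splats every localization as a
#' unit-mass 2-D Gaussian of width `uncertainty_nm`, integrated over
#' render pixels (sum equals the row count up to edge losses).
#'
#' @param table localization `data.frame`.
#' @param render_px_nm render pixel size in nm (default 20, i.e. a
#'   roughly 20-nm resolution reconstruction).
#' @param mode `"histogram"` or `"gaussian"`.
#' @param field_nm extent `c(width_nm, height_nm)` of the output; inferred
#'   from the data when `NULL`.
#' @return Numeric matrix (rows = y bins, cols = x bins).
#' @export
render_superres <- function(table, render_px_nm = 20,
                            mode = c("histogram", "gaussian"),
                            field_nm = NULL) {
  mode <- match.arg(mode)
  if (render_px_nm <= 0) stop_fq("fq_param", "'render_px_nm' must be > 0")
  if (is.null(field_nm)) {
    if (is.null(table) || nrow(table) == 0L)
      stop_fq("fq_param", "cannot infer the field extent from an empty table")
    field_nm <- c(max(table$x_nm), max(table$y_nm)) + render_px_nm
  }
  nx <- max(1L, ceiling(field_nm[1] / render_px_nm))
  ny <- max(1L, ceiling(field_nm[2] / render_px_nm))
  img <- matrix(0, ny, nx)
  if (is.null(table) || nrow(table) == 0L) return(img)
  if (mode == "histogram") {
    ix <- pmin(pmax(floor(table$x_nm / render_px_nm), 0), nx - 1) + 1L
    iy <- pmin(pmax(floor(table$y_nm / render_px_nm), 0), ny - 1) + 1L
    for (k in seq_len(nrow(table))) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1
    return(img)
  }
  for (k in seq_len(nrow(table))) {
    sd_px <- max(table$uncertainty_nm[k], 1e-6) / render_px_nm
    x <- table$x_nm[k] / render_px_nm
    y <- table$y_nm[k] / render_px_nm
    r <- ceiling(4 * sd_px) + 1L
    jj <- max(1L, floor(x) - r):min(nx, floor(x) + r + 1L)
    ii <- max(1L, floor(y) - r):min(ny, floor(y) + r + 1L)
    wx <- pnorm((jj - x) / sd_px) - pnorm((jj - 1 - x) / sd_px)
    wy <- pnorm((ii - y) / sd_px) - pnorm((ii - 1 - y) / sd_px)
    img[ii, jj] <- img[ii, jj] + outer(wy, wx)
  }
  img
}
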