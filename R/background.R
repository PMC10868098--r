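#' Rolling-ball background estimation and subtraction
#'
#' Estimates the smooth background of a fluorescence image as the
#' grayscale opening with a flat disk structuring element
#' (offsets `di^2 + dj^2 <= radius^2`): an erosion (minimum filter)
#' followed by a dilation (maximum filter), out-of-bounds neighbors
#' ignored. This is the common flat-disk approximation of the classic
#' rolling-ball background filter; at the default radius of 15 px the
#' exact ball geometry is irrelevant for diffraction-scale spots. The
#' background never exceeds the image pointwise and the operator is
#' idempotent.
#'
#' @param image 2-D numeric matrix.
#' @param radius_px disk radius in pixels (`>= 1`, at most the smaller
#'   image dimension).
#' @return `rolling_ball_background`: the background image;
#'   `subtract_background`: `image - background`, clipped at 0.
#' @export
rolling_ball_background <- function(image, radius_px = 15) {
  if (!is.matrix(image)) stop_fq("fq_param", "'image' must be a matrix")
  if (radius_px < 1) stop_fq("fq_param", "'radius_px' must be >= 1")
  if (radius_px > min(dim(image)))
    stop_fq("fq_param", "'radius_px' larger than the image")
  cpp_disk_opening(image, as.integer(radius_px))
}

#' @rdname rolling_ball_background
#' @export
subtract_background <- function(image, radius_px = 15) {
  pmax(image - rolling_ball_background(image, radius_px), 0)
}

#' F1-optimal intensity threshold against a ground-truth signal mask
#'
#' Searches the image's unique intensity values for the threshold `tau`
#' maximizing the F1 score of the pixel classification `image > tau`
#' against `truth_mask`; ties are broken toward the smaller threshold.
#' Used to build calibration data for [fit_threshold_model()] from
#' simulated images where true signal pixels are known.
#'
#' @param image 2-D numeric matrix.
#' @param truth_mask logical matrix marking true signal pixels.
#' @return The optimal threshold (numeric scalar).
#' @export
optimal_threshold <- function(image, truth_mask) {
  if (!any(truth_mask))
    stop_fq("fq_degenerate", "empty truth mask: optimum threshold undefined")
  vals <- sort(unique(as.vector(image)))
  if (length(vals) < 2L)
    stop_fq("fq_degenerate", "constant image: no separating threshold")
  ord <- order(image, decreasing = TRUE)
  pos <- as.vector(truth_mask)[ord]
  iv <- as.vector(image)[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  n_pos <- sum(truth_mask)
  # candidates: predicted positive = pixels with intensity > tau, i.e. for
  # tau = vals[k] the first `last index with iv > vals[k]` pixels in `ord`
  n_above <- length(iv) - findInterval(vals, sort(iv))
  f1 <- vapply(n_above, function(m) {
    if (m == 0) return(0)
    2 * tp[m] / (2 * tp[m] + fp[m] + (n_pos - tp[m]))
  }, numeric(1))
  vals[which.max(f1)]   # which.max takes the first (smallest tau) on ties
}

#' Linear background-threshold model
#'
#' Regresses the optimum threshold of calibration images on their mean and
#' standard deviation (ordinary least squares with intercept), emulating a
#' preset regression model that predicts the background threshold of a new
#' image from its summary statistics alone. The quality of the calibration
#' is recorded as the Pearson correlation `r` between fitted and observed
#' optimum thresholds.
#'
#' @param calibration `data.frame` (or matrix) with columns `mean`, `sd`,
#'   `tau_opt` — one row per calibration image (`>= 3` rows).
#' @return An object of class `threshold_model` with fields `coef_mean`,
#'   `coef_sd`, `intercept`, `r`, `n_calibration` and `residual_q95` (95th
#'   percentile of the absolute calibration residuals).
#' @export
fit_threshold_model <- function(calibration) {
  calibration <- as.data.frame(calibration)
  need <- c("mean", "sd", "tau_opt")
  if (!all(need %in% names(calibration)))
    stop_fq("fq_schema", "calibration needs columns mean, sd, tau_opt")
  if (nrow(calibration) < 3L)
    stop_fq("fq_param", "need at least 3 calibration points")
  X <- cbind(1, calibration$mean, calibration$sd)
  if (qr(X)$rank < 3L)
    stop_fq("fq_rank", "collinear calibration design (rank-deficient)")
  fit <- lm(tau_opt ~ mean + sd, data = calibration)
  fitted <- unname(fit$fitted.values)
  resid <- unname(fit$residuals)
  r <- suppressWarnings(cor(fitted, calibration$tau_opt))
  if (is.na(r) && max(abs(resid)) < 1e-8) r <- 1
  structure(list(coef_mean = unname(coef(fit)["mean"]),
                 coef_sd = unname(coef(fit)["sd"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r = r, n_calibration = nrow(calibration),
                 residual_q95 = unname(quantile(abs(resid), 0.95))),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> tau = %.4g * mean + %.4g * sd + %.4g  (r = %.3f, n = %d)\n",
    x$coef_mean, x$coef_sd, x$intercept, x$r, x$n_calibration))
  invisible(x)
}

#' Predict the background threshold of an image
#'
#' Applies a fitted [fit_threshold_model()]: `tau = coef_mean * mean(image)
#' + coef_sd * sd(image) + intercept`, floored at 0.
#'
#' @param model a `threshold_model`.
#' @param image 2-D numeric matrix.
#' @return Threshold `tau >= 0`.
#' @export
estimate_threshold <- function(model, image) {
  stopifnot(inherits(model, "threshold_model"))
  v <- as.vector(image)
  max(0, model$coef_mean * mean(v) + model$coef_sd * sd(v) + model$intercept)
}

#' Apply an intensity threshold
#'
#' Strict comparison: pixels `<= tau` are set to 0, pixels `> tau` pass
#' unchanged.
#'
#' @param image numeric matrix.
#' @param tau threshold (`>= 0`).
#' @export
apply_threshold <- function(image, tau) {
  if (tau < 0) stop_fq("fq_param", "'tau' must be >= 0")
  image * (image > tau)
}

#' Build threshold-calibration data from simulated frames
#'
#' Generates `n_images` synthetic single frames spanning a range of
#' background levels (uniformly drawn offset and amplitude), each with a
#' handful of active emitters, computes the F1-optimal threshold of every
#' frame against its true signal mask and returns the calibration table
#' together with the fitted [fit_threshold_model()].
#'
#' @param n_images number of calibration frames (default 20).
#' @param params a [sim_params()] supplying field size, PSF, photon and
#'   noise settings.
#' @param seed RNG seed.
#' @param offset_range,amplitude_range background ranges sampled across
#'   the calibration set.
#' @param n_emitters active emitters per calibration frame.
#' @param mask_level true signal pixels are those whose noiseless emitter
#'   contribution exceeds this fraction of the frame's peak contribution.
#' @param subtract background handling before measuring mean, SD and the
#'   optimum threshold. The default (`"none"`, raw frames) emulates a
#'   background-threshold regression on whole images, whose
#'   fitted-vs-optimum correlation is dominated by the autofluorescence
#'   level; `"background_field"` subtracts each frame's known clean
#'   background (matching the temporal-median preprocessing of
#'   [localize_stack()]); `"rolling_ball"` subtracts a per-frame
#'   rolling-ball background of radius `subtract_radius_px`. A model
#'   intended for frame-wise localization should be calibrated with the
#'   matching subtraction and a conservative core mask
#'   (see [detection_threshold_model()]).
#' @param subtract_radius_px rolling-ball radius for
#'   `subtract = "rolling_ball"`.
#' @return list with elements `model` (a `threshold_model`) and
#'   `calibration` (`data.frame` with `mean`, `sd`, `tau_opt`).
#' @export
calibrate_threshold_model <- function(n_images = 20, params = sim_params(),
                                      seed = 1, offset_range = c(50, 300),
                                      amplitude_range = c(10, 40),
                                      n_emitters = 5, mask_level = 0.2,
                                      subtract = c("none", "background_field",
                                                   "rolling_ball"),
                                      subtract_radius_px = 4) {
  subtract <- match.arg(subtract)
  set.seed(seed)
  n <- params$field_px
  p <- params$pixel_size_nm
  sig_px <- params$psf_sigma_nm / p
  cal <- data.frame(mean = numeric(n_images), sd = numeric(n_images),
                    tau_opt = numeric(n_images))
  for (i in seq_len(n_images)) {
    offset <- runif(1, offset_range[1], offset_range[2])
    amp <- runif(1, amplitude_range[1], amplitude_range[2])
    bg <- make_background_field(n, amp, params$background_corr_len_px, offset)
    margin <- 5
    em <- data.frame(
      x_nm = runif(n_emitters, margin, n - margin) * p,
      y_nm = runif(n_emitters, margin, n - margin) * p,
      photons = rpois(n_emitters, params$mean_photons))
    contrib <- cpp_expected_frame(n, n, em$x_nm / p, em$y_nm / p,
                                  em$photons, sig_px)
    truth_mask <- contrib > mask_level * max(contrib)
    img <- synthesize_frame(em, params$psf_sigma_nm, p, bg,
                            read_noise_sd = params$read_noise_sd)
    if (subtract == "background_field") img <- pmax(img - bg, 0)
    if (subtract == "rolling_ball")
      img <- subtract_background(img, subtract_radius_px)
    cal$mean[i] <- mean(img)
    cal$sd[i] <- sd(as.vector(img))
    cal$tau_opt[i] <- optimal_threshold(img, truth_mask)
  }
  list(model = fit_threshold_model(cal), calibration = cal)
}
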