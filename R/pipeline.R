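#' Quantify one field along the super-resolution path
#'
#' Full SR pipeline for one simulated or acquired field: segment nuclei
#' from the DAPI projection, localize emitters in the HER2 and CEP17
#' stacks (detection threshold predicted per frame by `tau_model`),
#' cluster the localizations into signals, annotate estimated counts, and
#' summarize per-nucleus counts into the sample-level metrics.
#'
#' @param field a [simulate_field()] result, or a list with `her2`,
#'   `cep17`, `dapi` [fish_stack()]s.
#' @param tau_model a [fit_threshold_model()] regression predicting the
#'   per-frame detection threshold; built by [detection_threshold_model()]
#'   when `NULL`.
#' @param eps_nm,min_pts clustering parameters
#'   ([cluster_localizations()]).
#' @param isolation_extent_nm SR ambiguity extent threshold
#'   ([estimate_cluster_count()]).
#' @param psf_sigma_nm expected PSF sigma (nm).
#' @param min_area_px smallest nucleus kept by segmentation.
#' @param min_strength_frac localization clusters weaker than this
#'   fraction of the single-signal reference strength are dropped as
#'   noise coincidences (a real locus blinks throughout the whole
#'   acquisition).
#' @param ... further arguments passed to [localize_stack()].
#' @return list with `result` ([summarize_counts()]), `counts`
#'   (per-nucleus), `nuclei`, annotated `her2`/`cep17` signal sets and
#'   the raw localization tables.
#' @export
quantify_sr_field <- function(field, tau_model = NULL, eps_nm = 150,
                              min_pts = 3, isolation_extent_nm = 120,
                              psf_sigma_nm = 130, min_area_px = 40,
                              min_strength_frac = 0.25, ...) {
  if (is.null(tau_model)) tau_model <- detection_threshold_model()
  nuclei <- segment_nuclei(widefield_projection(field$dapi),
                           min_area_px = min_area_px,
                           pixel_size_nm = field$dapi$pixel_size_nm)
  locs_h <- filter_localizations(
    localize_stack(field$her2, tau_model = tau_model,
                   psf_sigma_nm = psf_sigma_nm, ...), psf_sigma_nm)
  locs_c <- filter_localizations(
    localize_stack(field$cep17, tau_model = tau_model,
                   psf_sigma_nm = psf_sigma_nm, ...), psf_sigma_nm)
  finalize <- function(locs, channel) {
    sig <- cluster_localizations(locs, eps_nm, min_pts, channel)
    if (nrow(sig) > 0) {
      # a FISH locus blinks throughout the acquisition; components far
      # below the single-signal strength are noise coincidences
      ref <- reference_strength(sig)
      sig <- sig[sig$strength >= min_strength_frac * ref, , drop = FALSE]
      sig <- annotate_signal_counts(sig, reference = ref,
                                    isolation_extent_nm = isolation_extent_nm)
    } else {
      sig <- annotate_signal_counts(sig,
                                    isolation_extent_nm = isolation_extent_nm)
    }
    sig
  }
  sig_h <- finalize(locs_h, "HER2")
  sig_c <- finalize(locs_c, "CEP17")
  counts <- count_per_nucleus(sig_h, sig_c, nuclei)
  list(result = summarize_counts(counts), counts = counts, nuclei = nuclei,
       her2 = sig_h, cep17 = sig_c,
       localizations = list(HER2 = locs_h, CEP17 = locs_c))
}

#' Detection-grade threshold model for frame-wise localization
#'
#' Calibrates a [fit_threshold_model()] regression under the same
#' conditions the frame-wise localization path operates in: rolling-ball
#' subtracted frames (radius 4 px, the [localize_stack()] default), a
#' couple of active emitters per frame, and a conservative signal mask
#' (core PSF pixels, 50% of peak) so the predicted thresholds sit above
#' the shot-noise maxima that would otherwise percolate into spurious
#' localization clusters.
#'
#' @param params acquisition model ([sim_params()]); field size, PSF,
#'   photon and noise settings should match the data to be localized.
#' @param seed RNG seed for the calibration set.
#' @param n_images number of calibration frames.
#' @return A `threshold_model`.
#' @export
detection_threshold_model <- function(params = sim_params(), seed = 1,
                                      n_images = 20) {
  calibrate_threshold_model(n_images, params, seed = seed, n_emitters = 2,
                            mask_level = 0.5, subtract = "rolling_ball",
                            subtract_radius_px = 4)$model
}

#' Quantify one field along the conventional-resolution path
#'
#' The diffraction-limited counterpart of [quantify_sr_field()]: signals
#' are detected on the widefield projections of the raw stacks (no
#' super-resolution processing) after rolling-ball background
#' subtraction, and any spot implying more than four signals is
#' ambiguous.
#'
#' The conventional image of each signal channel is the field's
#' conventional-exposure snapshot when available (`field$conventional`,
#' as produced by [simulate_field()]); otherwise the mean
#' [widefield_projection()] of the raw stack is used.
#'
#' @inheritParams quantify_sr_field
#' @param radius_px rolling-ball radius for the conventional images
#'   (default 15).
#' @param tau optional fixed detection threshold on the subtracted
#'   images (a robust default is derived per image when `NULL`).
#' @param ... further arguments passed to [detect_spots_widefield()].
#' @export
quantify_cr_field <- function(field, radius_px = 15, tau = NULL,
                              min_area_px = 40, ...) {
  p <- field$her2$pixel_size_nm
  nuclei <- segment_nuclei(widefield_projection(field$dapi),
                           min_area_px = min_area_px,
                           pixel_size_nm = field$dapi$pixel_size_nm)
  conv <- function(ch, stack) {
    if (!is.null(field$conventional[[ch]])) field$conventional[[ch]]
    else widefield_projection(stack)
  }
  sig_h <- detect_spots_widefield(conv("HER2", field$her2),
                                  radius_px = radius_px, tau = tau,
                                  pixel_size_nm = p, channel = "HER2", ...)
  sig_c <- detect_spots_widefield(conv("CEP17", field$cep17),
                                  radius_px = radius_px, tau = tau,
                                  pixel_size_nm = p, channel = "CEP17", ...)
  counts <- count_per_nucleus(sig_h, sig_c, nuclei)
  list(result = summarize_counts(counts), counts = counts, nuclei = nuclei,
       her2 = sig_h, cep17 = sig_c)
}

#' Match segmented nuclei to simulation ground truth
#'
#' Pairs every true nucleus with the segmentation label found at its
#' centroid pixel (0 when the centroid fell on background).
#'
#' @param nucleus_map a [segment_nuclei()] result.
#' @param truth the `truth` element of a [simulate_field()].
#' @return `data.frame` with `truth_id` and `seg_id`.
#' @export
match_nuclei_to_truth <- function(nucleus_map, truth) {
  p <- nucleus_map$pixel_size_nm
  ri <- floor(truth$nuclei$y_nm / p) + 1L
  ci <- floor(truth$nuclei$x_nm / p) + 1L
  data.frame(truth_id = truth$nuclei$id,
             seg_id = nucleus_map$labels[cbind(ri, ci)])
}

#' Per-nucleus agreement between measured and true counts
#'
#' Joins measured per-nucleus counts to the simulation truth via
#' [match_nuclei_to_truth()] and reports, per true nucleus, the measured
#' and true `(H, C)`. Unmatched nuclei get `NA` measurements.
#'
#' @param counts a [count_per_nucleus()] table.
#' @param nucleus_map the [segment_nuclei()] map the counts refer to.
#' @param truth simulation ground truth.
#' @return `data.frame` with columns `nucleus_id`, `H_true`, `C_true`,
#'   `H`, `C`, `exact` (both channels exactly recovered).
#' @export
count_recovery <- function(counts, nucleus_map, truth) {
  mm <- match_nuclei_to_truth(nucleus_map, truth)
  out <- data.frame(nucleus_id = truth$per_nucleus$nucleus_id,
                    H_true = truth$per_nucleus$H,
                    C_true = truth$per_nucleus$C,
                    H = NA_real_, C = NA_real_)
  for (k in seq_len(nrow(out))) {
    sid <- mm$seg_id[mm$truth_id == out$nucleus_id[k]]
    if (length(sid) == 1 && sid > 0) {
      row <- counts[counts$nucleus_id == sid, ]
      if (nrow(row) == 1) { out$H[k] <- row$H; out$C[k] <- row$C }
    }
  }
  out$exact <- !is.na(out$H) & out$H == out$H_true &
    !is.na(out$C) & out$C == out$C_true
  out
}
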