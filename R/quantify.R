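#' Segment nuclei from a DAPI projection
#'
#' Deterministic chain: Gaussian smoothing, Otsu global threshold, hole
#' filling, distance-transform watershed to split touching objects, area
#' filter, and relabeling to contiguous ids `1..K`.
#'
#' @param dapi_projection 2-D DAPI image (e.g.
#'   [widefield_projection()] of the DAPI stack).
#' @param min_area_px minimum object area kept (px).
#' @param blur_sigma_px smoothing sigma before thresholding.
#' @param pixel_size_nm pixel pitch (nm), carried into the centroids.
#' @param watershed_tolerance minimum object-separating depth of the
#'   distance map passed to the watershed.
#' @return An object of class `nucleus_map`: list with `labels` (integer
#'   matrix, 0 = background), `nuclei` (`data.frame` of `id`, `x_nm`,
#'   `y_nm`, `area_px`) and `pixel_size_nm`. An all-background image
#'   yields an empty map, not an error.
#' @export
segment_nuclei <- function(dapi_projection, min_area_px = 40,
                           blur_sigma_px = 1, pixel_size_nm = 100,
                           watershed_tolerance = 1) {
  img <- dapi_projection
  empty <- function() structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                                     nuclei = data.frame(id = integer(0),
                                                         x_nm = numeric(0),
                                                         y_nm = numeric(0),
                                                         area_px = numeric(0)),
                                     pixel_size_nm = pixel_size_nm),
                                class = "nucleus_map")
  rng <- range(img)
  if (diff(rng) <= 0) return(empty())
  norm <- (img - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = blur_sigma_px)
  th <- EBImage::otsu(sm)
  bw <- sm > th
  if (!any(bw)) return(empty())
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::imageData(EBImage::watershed(dm,
                                               tolerance = watershed_tolerance))
  ids <- setdiff(unique(as.vector(lab)), 0)
  keep <- ids[vapply(ids, function(i) sum(lab == i), numeric(1)) >= min_area_px]
  out <- matrix(0L, nrow(img), ncol(img))
  nuclei <- data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                       area_px = numeric(0))
  for (k in seq_along(keep)) {
    sel <- lab == keep[k]
    out[sel] <- k
    idx <- which(sel, arr.ind = TRUE)
    nuclei <- rbind(nuclei,
                    data.frame(id = k,
                               x_nm = mean(idx[, 2] - 0.5) * pixel_size_nm,
                               y_nm = mean(idx[, 1] - 0.5) * pixel_size_nm,
                               area_px = nrow(idx)))
  }
  structure(list(labels = out, nuclei = nuclei,
                 pixel_size_nm = pixel_size_nm),
            class = "nucleus_map")
}

#' @export
print.nucleus_map <- function(x, ...) {
  cat(sprintf("<nucleus_map> %d nuclei in a %d x %d px field\n",
              nrow(x$nuclei), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

empty_signal_set <- function(channel = NA_character_, mode = "sr") {
  structure(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                       strength = numeric(0), extent_nm = numeric(0)),
            channel = channel, mode = mode)
}

#' Cluster localizations into discrete FISH signals
#'
#' Density-based clustering: two localizations are linked when within
#' `eps_nm` of each other and signals are the connected components with at
#' least `min_pts` members; smaller components are discarded as noise.
#' Each signal carries its centroid, its strength (number of
#' localizations) and its spatial extent (RMS distance to the centroid).
#'
#' @param table localization `data.frame`.
#' @param eps_nm linkage distance (default 150 nm, about the separation
#'   the super-resolution reconstruction can resolve).
#' @param min_pts minimum localizations per signal (default 3).
#' @param channel optional channel label attached to the result.
#' @return A `data.frame` signal set (`x_nm`, `y_nm`, `strength`,
#'   `extent_nm`) with attributes `channel` and `mode = "sr"`. The
#'   extent is a robust RMS radius (1.2 times the median distance to
#'   the centroid), insensitive to the occasional artifact fit.
#' @export
cluster_localizations <- function(table, eps_nm = 150, min_pts = 3,
                                  channel = NA_character_) {
  if (eps_nm <= 0) stop_fq("fq_param", "'eps_nm' must be > 0")
  if (is.null(table) || nrow(table) == 0L)
    return(empty_signal_set(channel, "sr"))
  lab <- cpp_cluster_points(table$x_nm, table$y_nm, eps_nm)
  keep <- as.integer(names(which(table(lab) >= min_pts)))
  out <- do.call(rbind, lapply(keep, function(l) {
    sel <- lab == l
    cx <- mean(table$x_nm[sel]); cy <- mean(table$y_nm[sel])
    d <- sqrt((table$x_nm[sel] - cx)^2 + (table$y_nm[sel] - cy)^2)
    # robust RMS radius: 1.2 * median distance equals the RMS radius for a
    # 2-D Gaussian cloud but ignores the few artifact fits in the tails
    data.frame(x_nm = cx, y_nm = cy, strength = sum(sel),
               extent_nm = 1.2 * median(d))
  }))
  if (is.null(out)) return(empty_signal_set(channel, "sr"))
  structure(out[order(out$x_nm, out$y_nm), , drop = FALSE],
            channel = channel, mode = "sr")
}

#' Estimate how many FISH signals one detected spot represents
#'
#' A spot whose strength (localizations for the super-resolution path,
#' integrated intensity for the conventional path) is a multiple of the
#' reference single-signal strength is counted as that multiple
#' (`round(strength / reference)`, floored at 1). A spot implying more
#' than four signals whose spatial extent exceeds `isolation_extent_nm`
#' cannot be resolved into individual signals: it is flagged ambiguous
#' and reported as "more than four" (count 5 with the flag set).
#'
#' @param strength spot strength(s).
#' @param reference single-signal reference strength (`> 0`), typically
#'   [reference_strength()] of the same sample.
#' @param extent_nm spot extent(s), same length as `strength`.
#' @param isolation_extent_nm extent above which a `> 4`-signal spot is
#'   unresolvable. 120 nm (just under the PSF sigma) for the
#'   super-resolution path, where genuine multi-signal clusters are tens
#'   of nm wide; 0 for the conventional path, where any `> 4`-signal spot
#'   is by construction diffraction-blurred.
#' @return `data.frame` with `est_count` (integer) and `ambiguous`
#'   (logical; implies `est_count == 5`, meaning "more than four").
#' @export
estimate_cluster_count <- function(strength, reference, extent_nm,
                                   isolation_extent_nm = 120) {
  if (!is.finite(reference) || reference <= 0)
    stop_fq("fq_calibration", "non-positive reference signal strength")
  est <- pmax(1L, as.integer(round(strength / reference)))
  ambiguous <- est > 4L & extent_nm > isolation_extent_nm
  est[ambiguous] <- 5L
  data.frame(est_count = est, ambiguous = ambiguous)
}

#' Reference single-signal strength of a sample
#'
#' Median strength over the sample's isolated signals, operationalized as
#' those no stronger than 2.5 times the overall median (which excludes
#' multi-signal clusters from the reference).
#'
#' @param signals a signal set ([cluster_localizations()] or
#'   [detect_spots_widefield()] output).
#' @export
reference_strength <- function(signals) {
  if (nrow(signals) == 0L)
    stop_fq("fq_calibration", "no signals to calibrate a reference from")
  med <- median(signals$strength)
  median(signals$strength[signals$strength <= 2.5 * med])
}

#' Annotate a signal set with estimated counts and ambiguity flags
#'
#' @inheritParams estimate_cluster_count
#' @param signals a signal set.
#' @param reference single-signal reference; computed by
#'   [reference_strength()] when `NULL`.
#' @export
annotate_signal_counts <- function(signals, reference = NULL,
                                   isolation_extent_nm = 120) {
  if (nrow(signals) == 0L) {
    signals$est_count <- integer(0)
    signals$ambiguous <- logical(0)
    return(signals)
  }
  if (is.null(reference)) reference <- reference_strength(signals)
  est <- estimate_cluster_count(signals$strength, reference,
                                signals$extent_nm, isolation_extent_nm)
  signals$est_count <- est$est_count
  signals$ambiguous <- est$ambiguous
  signals
}

#' Detect FISH signals on a conventional-resolution projection
#'
#' The conventional path: rolling-ball background subtraction, an
#' intensity threshold (fixed, predicted by a [fit_threshold_model()], or
#' a robust `median + 6 * MAD` default), local-maxima detection, and
#' per-spot strength (integrated window intensity) and extent
#' (intensity-weighted RMS radius). Counts are annotated with
#' `isolation_extent_nm = 0`: a diffraction-limited spot implying more
#' than four signals is always ambiguous.
#'
#' @param projection 2-D image ([widefield_projection()] output).
#' @param radius_px rolling-ball radius (default 15).
#' @param tau fixed threshold on the background-subtracted image.
#' @param tau_model optional `threshold_model` applied to the subtracted
#'   image (used when `tau` is `NULL`).
#' @param min_separation_px peak merge radius (px).
#' @param pixel_size_nm pixel pitch (nm).
#' @param window_px measurement window edge (odd).
#' @param reference optional single-signal reference intensity.
#' @param isolation_extent_nm see [estimate_cluster_count()].
#' @return An annotated signal set (attributes `channel`, `mode = "cr"`).
#' @export
detect_spots_widefield <- function(projection, radius_px = 15, tau = NULL,
                                   tau_model = NULL, min_separation_px = 2,
                                   pixel_size_nm = 100, window_px = 7,
                                   reference = NULL,
                                   isolation_extent_nm = 0,
                                   channel = NA_character_) {
  sub <- subtract_background(projection, radius_px)
  if (is.null(tau)) {
    tau <- if (!is.null(tau_model)) estimate_threshold(tau_model, sub)
    else {
      m <- stats::mad(as.vector(sub))
      if (m == 0) m <- sd(as.vector(sub))
      median(as.vector(sub)) + 6 * m
    }
  }
  peaks <- detect_candidates(sub, tau, min_separation_px)
  wh <- (window_px - 1) / 2
  h <- nrow(sub); w <- ncol(sub)
  out <- NULL
  for (k in seq_len(nrow(peaks))) {
    ri <- max(1, peaks$row[k] - wh):min(h, peaks$row[k] + wh)
    ci <- max(1, peaks$col[k] - wh):min(w, peaks$col[k] + wh)
    win <- sub[ri, ci, drop = FALSE]
    s <- sum(win)
    if (s <= 0) next
    cx <- sum(t(win) * (ci - 0.5)) / s
    cy <- sum(win * (ri - 0.5)) / s
    ext <- sqrt(sum(win * outer((ri - 0.5 - cy)^2, (ci - 0.5 - cx)^2, "+")) / s)
    out <- rbind(out, data.frame(x_nm = cx * pixel_size_nm,
                                 y_nm = cy * pixel_size_nm, strength = s,
                                 extent_nm = ext * pixel_size_nm))
  }
  if (is.null(out)) return(empty_signal_set(channel, "cr"))
  out <- structure(out, channel = channel, mode = "cr")
  annotate_signal_counts(out, reference, isolation_extent_nm)
}

#' Per-nucleus HER2 and CEP17 counts
#'
#' Assigns every signal to the nucleus whose mask contains its centroid
#' (signals outside all nuclei are discarded and tallied in the
#' `"n_outside"` attribute). Per nucleus, `H` and `C` are the summed
#' estimated counts of the assigned HER2 / CEP17 signals, the ambiguity
#' flags propagate, and CEP17 is countable when at least one CEP17 signal
#' is present and none is ambiguous.
#'
#' @param her2,cep17 annotated signal sets (see
#'   [annotate_signal_counts()]).
#' @param nuclei a [segment_nuclei()] map sharing the coordinate frame.
#' @return `data.frame` of class `nucleus_counts` with one row per
#'   nucleus: `nucleus_id`, `H`, `her2_ambiguous`, `C`, `cep17_ambiguous`,
#'   `cep17_countable`.
#' @export
count_per_nucleus <- function(her2, cep17, nuclei) {
  stopifnot(inherits(nuclei, "nucleus_map"))
  p <- nuclei$pixel_size_nm
  lab <- nuclei$labels
  assign_lab <- function(sig) {
    if (nrow(sig) == 0L) return(integer(0))
    ri <- floor(sig$y_nm / p) + 1L
    ci <- floor(sig$x_nm / p) + 1L
    ok <- ri >= 1 & ri <= nrow(lab) & ci >= 1 & ci <= ncol(lab)
    l <- integer(nrow(sig))
    l[ok] <- lab[cbind(ri[ok], ci[ok])]
    l
  }
  lh <- assign_lab(her2)
  lc <- assign_lab(cep17)
  ids <- nuclei$nuclei$id
  out <- data.frame(
    nucleus_id = ids,
    H = vapply(ids, function(i) sum(her2$est_count[lh == i]), numeric(1)),
    her2_ambiguous = vapply(ids, function(i)
      any(her2$ambiguous[lh == i]), logical(1)),
    C = vapply(ids, function(i) sum(cep17$est_count[lc == i]), numeric(1)),
    cep17_ambiguous = vapply(ids, function(i)
      any(cep17$ambiguous[lc == i]), logical(1)))
  out$cep17_countable <- out$C >= 1 & !out$cep17_ambiguous
  structure(out, n_outside = sum(lh == 0) + sum(lc == 0),
            class = c("nucleus_counts", "data.frame"))
}

#' Summarize per-nucleus counts into the nine sample-level FISH metrics
#'
#' Computes, for one sample: the number of nuclei with countable
#' (non-ambiguous) HER2 signals and the number with ambiguous HER2
#' signals; total HER2 signals and HER2 signals per nucleus over the
#' countable nuclei (ambiguous nuclei are tallied separately, not summed);
#' the same four CEP17 metrics; and the HER2/CEP17 ratio, computed over
#' the nuclei in which CEP17 signals are countable
#' (`sum(H) / sum(C)` on those nuclei). When no nucleus has countable
#' CEP17 the ratio is undefined and returned as `NA` with a reason.
#'
#' @param counts a [count_per_nucleus()] table (`>= 1` nucleus).
#' @return A list of class `fish_result` with the nine metrics,
#'   `n_nuclei`, and `ratio_reason` (string, `NA` unless the ratio is
#'   undefined).
#' @export
summarize_counts <- function(counts) {
  if (nrow(counts) < 1L) stop_fq("fq_param", "need at least one nucleus")
  hc <- counts$H >= 1 & !counts$her2_ambiguous
  cc <- counts$C >= 1 & !counts$cep17_ambiguous
  elig <- counts$cep17_countable
  ratio <- NA_real_
  reason <- NA_character_
  if (!any(elig)) {
    reason <- "no nucleus with countable CEP17 signals"
  } else if (sum(counts$C[elig]) == 0) {
    reason <- "zero CEP17 signals in eligible nuclei"
  } else {
    ratio <- sum(counts$H[elig]) / sum(counts$C[elig])
  }
  res <- list(
    nuclei_with_her2 = sum(hc),
    nuclei_ambiguous_her2 = sum(counts$her2_ambiguous),
    her2_signals = sum(counts$H[hc]),
    her2_per_nucleus = if (any(hc)) sum(counts$H[hc]) / sum(hc) else NA_real_,
    nuclei_with_cep17 = sum(cc),
    nuclei_ambiguous_cep17 = sum(counts$cep17_ambiguous),
    cep17_signals = sum(counts$C[cc]),
    cep17_per_nucleus = if (any(cc)) sum(counts$C[cc]) / sum(cc) else NA_real_,
    ratio = ratio,
    n_nuclei = nrow(counts),
    ratio_reason = reason)
  structure(res, class = "fish_result")
}

FISH_METRICS <- c("nuclei_with_her2", "nuclei_ambiguous_her2",
                  "her2_signals", "her2_per_nucleus", "nuclei_with_cep17",
                  "nuclei_ambiguous_cep17", "cep17_signals",
                  "cep17_per_nucleus", "ratio")

#' @export
print.fish_result <- function(x, ...) {
  cat("<fish_result>\n")
  for (m in FISH_METRICS)
    cat(sprintf("  %-24s %s\n", m, format(x[[m]], digits = 4)))
  if (!is.na(x$ratio_reason))
    cat("  ratio undefined:", x$ratio_reason, "\n")
  invisible(x)
}

#' @export
as.data.frame.fish_result <- function(x, ...) {
  as.data.frame(x[FISH_METRICS])
}
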