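#' ASCO/CAP 2018 dual-probe ISH group assignment
#'
#' Partitions the (HER2/CEP17 ratio, mean HER2 signals per cell) plane
#' into the five dual-probe in situ hybridization groups of the 2018
#' ASCO/CAP HER2 testing guideline:
#' Group 1 (ratio >= 2.0, HER2/cell >= 4.0), Group 2 (ratio >= 2.0,
#' HER2/cell < 4.0; the historical "monosomy" pattern), Group 3
#' (ratio < 2.0, HER2/cell >= 6.0), Group 4 (ratio < 2.0,
#' HER2/cell in \[4.0, 6.0)) and Group 5 (ratio < 2.0, HER2/cell < 4.0).
#' The guideline's overlapping Group 3/4 boundary at 6.0 is resolved as
#' Group 4 = \[4.0, 6.0) so the five regions form a disjoint cover.
#'
#' @param ratio HER2/CEP17 ratio (`>= 0`); vectorized.
#' @param her2_per_cell mean HER2 signals per cell (`>= 0`); vectorized.
#' @return Integer group index 1-5.
#' @export
assign_group <- function(ratio, her2_per_cell) {
  if (any(!is.finite(ratio)) || any(!is.finite(her2_per_cell)) ||
      any(ratio < 0) || any(her2_per_cell < 0))
    stop_fq("fq_domain", "ratio and her2_per_cell must be finite and >= 0")
  ifelse(ratio >= 2,
         ifelse(her2_per_cell >= 4, 1L, 2L),
         ifelse(her2_per_cell >= 6, 3L,
                ifelse(her2_per_cell >= 4, 4L, 5L)))
}

#' ISH status implied by a dual-probe group
#'
#' Group 1 is ISH-positive and Group 5 ISH-negative on the hybridization
#' result alone; Groups 2-4 require further evaluation by
#' immunohistochemistry.
#'
#' @param group integer group 1-5; vectorized.
#' @return `"positive"`, `"negative"` or `"needs_ihc"`.
#' @export
ish_status <- function(group) {
  if (any(!group %in% 1:5)) stop_fq("fq_domain", "group must be in 1..5")
  c("positive", "needs_ihc", "needs_ihc", "needs_ihc", "negative")[group]
}

#' Integrate the IHC score into the overall HER2 status
#'
#' Groups 1 and 5 are decided by ISH alone. For Groups 2-4 the
#' concurrently reviewed IHC score adjudicates: IHC 0/1+ is negative and
#' IHC 3+ positive in all three groups; for IHC 2+ the guideline's
#' concurrent-review outcome applies (Group 2 negative, Group 3 positive,
#' Group 4 negative) and the result is flagged `guideline_default`.
#'
#' @param group integer group 1-5.
#' @param ihc_score IHC grade 0, 1, 2 or 3 (`NA` allowed for groups 1
#'   and 5); required for groups 2-4.
#' @return A list of class `ascocap_result`: `group`, `ish_status`,
#'   `overall_status`, `ihc_score`, `guideline_default`, and `annotation`
#'   (`"monosomy"` for Group 2).
#' @export
integrate_ihc <- function(group, ihc_score = NA) {
  if (!group %in% 1:5) stop_fq("fq_domain", "group must be in 1..5")
  ish <- ish_status(group)
  guideline_default <- FALSE
  if (group == 1) {
    overall <- "positive"
  } else if (group == 5) {
    overall <- "negative"
  } else {
    if (is.na(ihc_score))
      stop_fq("fq_incomplete", "group ", group,
              " requires an IHC score for the overall status")
    if (!ihc_score %in% 0:3) stop_fq("fq_domain", "IHC score must be 0..3")
    if (ihc_score <= 1) {
      overall <- "negative"
    } else if (ihc_score == 3) {
      overall <- "positive"
    } else {
      overall <- if (group == 3) "positive" else "negative"
      guideline_default <- TRUE
    }
  }
  structure(list(group = as.integer(group), ish_status = ish,
                 overall_status = overall,
                 ihc_score = if (is.na(ihc_score)) NA_integer_
                             else as.integer(ihc_score),
                 guideline_default = guideline_default,
                 annotation = if (group == 2) "monosomy" else NA_character_),
            class = "ascocap_result")
}

#' Classify one sample end to end
#'
#' Convenience wrapper: [assign_group()] on the sample's ratio and
#' per-cell HER2 count, then [integrate_ihc()]. `her2_per_cell` defaults
#' to the `her2_per_nucleus` metric of a [summarize_counts()] result.
#'
#' @param ratio HER2/CEP17 ratio, or a `fish_result`.
#' @param her2_per_cell mean HER2 signals per cell (ignored when `ratio`
#'   is a `fish_result`).
#' @param ihc_score IHC grade 0-3 (`NA` when not needed).
#' @return An `ascocap_result` (see [integrate_ihc()]) with the inputs
#'   echoed in `ratio` and `her2_per_cell`.
#' @export
classify_sample <- function(ratio, her2_per_cell = NULL, ihc_score = NA) {
  if (inherits(ratio, "fish_result")) {
    her2_per_cell <- ratio$her2_per_nucleus
    ratio <- ratio$ratio
  }
  if (is.na(ratio) || is.na(her2_per_cell))
    stop_fq("fq_incomplete",
            "ratio and her2_per_cell must be available to classify")
  g <- assign_group(ratio, her2_per_cell)
  out <- integrate_ihc(g, ihc_score)
  out$ratio <- ratio
  out$her2_per_cell <- her2_per_cell
  out
}

#' @export
print.ascocap_result <- function(x, ...) {
  cat(sprintf("<ascocap_result> Group %d (%s); overall HER2 %s%s\n",
              x$group, x$ish_status, x$overall_status,
              if (isTRUE(x$guideline_default)) " [guideline default]" else ""))
  invisible(x)
}
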