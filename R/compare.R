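#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the non-zero paired differences with
#' midrank handling of ties. For `m <= 25` non-zero differences the
#' p-value is exact, computed from the full conditional distribution of
#' the positive-rank sum over all `2^m` equiprobable sign patterns (via a
#' generating-function recursion over the doubled midranks, which
#' enumerates that distribution exactly); above 25 a normal approximation
#' with tie-corrected variance is used (no continuity correction).
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @param exact_max largest `m` for which the exact distribution is used.
#' @return list with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided), `n_used` (non-zero differences) and `method`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25) {
  if (length(x) != length(y) || length(x) < 1)
    stop_fq("fq_param", "'x' and 'y' must be non-empty and equal length")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    stop_fq("fq_degenerate", "all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= exact_max) {
    # distribution of the positive-rank sum over all 2^m sign patterns;
    # doubled midranks keep the support integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)   # counts[s + 1] = #patterns with sum s
    counts[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), counts[seq_len(total + 1 - rr)])
      counts <- counts + shifted
    }
    probs <- counts / 2^m
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[seq(w2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = W, p_value = p, n_used = m, method = method)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum test with midrank ties. For `n1 + n2 <= 12` the
#' p-value is exact by literal enumeration of all `choose(n1+n2, n1)`
#' group labelings of the observed (tied) ranks; above that a normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max largest `n1 + n2` enumerated exactly.
#' @return list with `statistic` (U for the first sample), `p_value`,
#'   and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop_fq("fq_param", "both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= exact_max) {
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p_le <- mean(us <= U + 1e-9)
    p_ge <- mean(us >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Pearson chi-squared test of independence
#'
#' Pearson's X^2 on an r x c table of counts with expectations from the
#' row/column margins and *no* continuity correction, the convention used
#' for the cohort contingency comparisons.
#'
#' @param table matrix of non-negative integer counts with at least two
#'   non-zero rows and columns.
#' @return list with `statistic` (X^2), `df` and `p_value` (upper tail).
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_fq("fq_param", "counts must be non-negative integers")
  rs <- rowSums(table); cs <- colSums(table)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2)
    stop_fq("fq_degenerate", "need at least two non-zero rows and columns")
  n <- sum(table)
  E <- outer(rs, cs) / n
  X2 <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = X2, df = df, p_value = pchisq(X2, df, lower.tail = FALSE))
}

#' Cohort report: conventional vs super-resolution quantification
#'
#' For a cohort of samples quantified both ways, tabulates every
#' sample-level FISH metric as median (min, max) per resolution within
#' each routine-status stratum, attaches the paired Wilcoxon signed-rank
#' p-value per metric (NA when fewer than two informative pairs), and
#' builds the cross-resolution contingency table of ASCO/CAP groups
#' (samples with an undefined ratio are tallied as "Unevaluable").
#' A p-value below `alpha` (default 0.05) is annotated as significant.
#'
#' @param samples list of per-sample lists with elements `sample_id`,
#'   `cr` and `sr` ([summarize_counts()] results), `routine_status`
#'   (e.g. "positive"/"negative") and optional `ihc`.
#' @param alpha significance convention carried into the report.
#' @return list of class `cohort_report`: `summary` (long `data.frame`),
#'   `tests` (per-stratum, per-metric Wilcoxon p), `contingency`
#'   (CR groups x SR groups), `alpha`, and `conventions`.
#' @export
cohort_report <- function(samples, alpha = 0.05) {
  if (length(samples) < 1) stop_fq("fq_param", "need at least one sample")
  grab <- function(s, which) vapply(FISH_METRICS, function(m)
    as.numeric(s[[which]][[m]]), numeric(1))
  strata <- vapply(samples, function(s) as.character(s$routine_status),
                   character(1))
  summary <- NULL; tests <- NULL
  for (st in unique(strata)) {
    sel <- which(strata == st)
    cr <- vapply(samples[sel], grab, numeric(length(FISH_METRICS)), "cr")
    sr <- vapply(samples[sel], grab, numeric(length(FISH_METRICS)), "sr")
    if (length(sel) == 1) { cr <- matrix(cr); sr <- matrix(sr) }
    for (k in seq_along(FISH_METRICS)) {
      for (res in c("cr", "sr")) {
        v <- if (res == "cr") cr[k, ] else sr[k, ]
        v <- v[is.finite(v)]
        summary <- rbind(summary, data.frame(
          stratum = st, metric = FISH_METRICS[k], resolution = res,
          n = length(v),
          median = if (length(v)) median(v) else NA_real_,
          min = if (length(v)) min(v) else NA_real_,
          max = if (length(v)) max(v) else NA_real_))
      }
      ok <- is.finite(cr[k, ]) & is.finite(sr[k, ])
      p <- NA_real_
      if (sum(ok) >= 2 && any(cr[k, ok] != sr[k, ok]))
        p <- wilcoxon_paired(cr[k, ok], sr[k, ok])$p_value
      tests <- rbind(tests, data.frame(
        stratum = st, metric = FISH_METRICS[k], n_pairs = sum(ok),
        p_value = p, significant = !is.na(p) & p < alpha))
    }
  }
  lv <- c(paste("Group", 1:5), "Unevaluable")
  gr <- function(s, which) {
    r <- s[[which]]
    if (is.na(r$ratio) || is.na(r$her2_per_nucleus)) return("Unevaluable")
    paste("Group", assign_group(r$ratio, r$her2_per_nucleus))
  }
  contingency <- table(
    factor(vapply(samples, gr, character(1), "cr"), levels = lv),
    factor(vapply(samples, gr, character(1), "sr"), levels = lv),
    dnn = c("conventional", "super_resolution"))
  structure(list(summary = summary, tests = tests,
                 contingency = contingency, alpha = alpha,
                 conventions = paste("two-sided tests; zero differences",
                                     "dropped, midrank ties; p <", alpha,
                                     "considered statistically significant")),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", length(unique(x$summary$stratum)), "stratum(s),",
      sum(x$contingency), "samples\n")
  sig <- x$tests[!is.na(x$tests$p_value) & x$tests$significant, ]
  if (nrow(sig))
    cat("  significant (p <", x$alpha, "):",
        paste(sig$stratum, sig$metric, collapse = "; "), "\n")
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `summary.csv`, `tests.csv`, `contingency.csv` and `report.json`
#' under `dir`.
#'
#' @param report a [cohort_report()].
#' @param dir output directory (created if needed).
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  write.csv(as.data.frame.matrix(report$contingency),
            file.path(dir, "contingency.csv"))
  jsonlite::write_json(list(summary = report$summary, tests = report$tests,
                            contingency = as.data.frame(report$contingency),
                            alpha = report$alpha,
                            conventions = report$conventions),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
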