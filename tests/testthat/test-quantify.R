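test_that("nucleus segmentation finds discs, ellipses and touching pairs", {
  # one bright disc
  img <- matrix(0, 64, 64)
  xs <- seq_len(64) - 0.5
  img[outer((xs - 20)^2, (xs - 30)^2, "+") <= 100] <- 1
  nm <- segment_nuclei(img, min_area_px = 30)
  expect_identical(nrow(nm$nuclei), 1L)
  expect_lt(abs(nm$nuclei$x_nm - 3000), 100)
  expect_lt(abs(nm$nuclei$y_nm - 2000), 100)

  # all-background image yields an empty map, not an error
  empty <- segment_nuclei(matrix(5, 32, 32))
  expect_identical(nrow(empty$nuclei), 0L)

  # five simulated ellipses recovered with areas close to truth
  fld <- simulate_field(small_params(seed = 31))
  nm5 <- segment_nuclei(widefield_projection(fld$dapi), min_area_px = 40)
  expect_identical(nrow(nm5$nuclei), 5L)
  mm <- match_nuclei_to_truth(nm5, fld$truth)
  expect_true(all(mm$seg_id > 0))
  for (k in seq_len(5)) {
    true_area <- sum(fld$truth$nucleus_mask == mm$truth_id[k])
    seg_area <- nm5$nuclei$area_px[nm5$nuclei$id == mm$seg_id[k]]
    expect_lt(abs(seg_area - true_area) / true_area, 0.2)
  }

  # two touching discs split by the watershed
  img2 <- matrix(0, 64, 64)
  img2[outer((xs - 32)^2, (xs - 24)^2, "+") <= 81] <- 1
  img2[outer((xs - 32)^2, (xs - 41)^2, "+") <= 81] <- 1
  nm2 <- segment_nuclei(img2, min_area_px = 30)
  expect_identical(nrow(nm2$nuclei), 2L)
})

test_that("localization clustering equals a brute-force linkage oracle", {
  expect_identical(nrow(cluster_localizations(NULL)), 0L)

  set.seed(41)
  mk <- function(cx, cy, n, sd = 15)
    data.frame(x_nm = rnorm(n, cx, sd), y_nm = rnorm(n, cy, sd))
  pts <- rbind(mk(1000, 1000, 20), mk(1500, 1010, 25), mk(3000, 2500, 3),
               data.frame(x_nm = 4000, y_nm = 4000))   # singleton = noise
  tab <- data.frame(frame = 0L, pts, sigma_nm = 130, photons = 1000,
                    background = 0, uncertainty_nm = 10)
  got <- cluster_localizations(tab, eps_nm = 150, min_pts = 3)
  expect_identical(nrow(got), 3L)
  expect_equal(sort(got$strength), c(3, 20, 25))

  # oracle: explicit pairwise linkage graph components
  d <- as.matrix(dist(pts))
  adj <- d <= 150
  g <- seq_len(nrow(pts))
  repeat {
    g2 <- apply(adj, 1, function(row) min(g[row]))
    if (identical(g2, g)) break
    g <- g2
  }
  keep <- table(g)[table(g) >= 3]
  expect_identical(nrow(got), length(keep))
  expect_equal(sort(got$strength), sort(as.numeric(keep)))

  # all points within eps of one centre form a single signal
  tight <- data.frame(frame = 0L, mk(2000, 2000, 12, 5), sigma_nm = 130,
                      photons = 1, background = 0, uncertainty_nm = 1)
  one <- cluster_localizations(tight, 150, 3)
  expect_identical(nrow(one), 1L)
  expect_lt(abs(one$x_nm - 2000), 10)
  expect_lt(one$extent_nm, 30)
})

test_that("cluster count estimation applies the more-than-four rule", {
  expect_equal(estimate_cluster_count(200, 200, 40),
               data.frame(est_count = 1L, ambiguous = FALSE))
  # twelve-fold strength with a broad footprint: reported as "more than 4"
  big <- estimate_cluster_count(2400, 200, 300, isolation_extent_nm = 120)
  expect_identical(big$est_count, 5L)
  expect_true(big$ambiguous)
  # same strength but compact (resolved at super-resolution): exact count
  tight <- estimate_cluster_count(2400, 200, 60, isolation_extent_nm = 120)
  expect_identical(tight$est_count, 12L)
  expect_false(tight$ambiguous)
  expect_equal(estimate_cluster_count(680, 200, 40)$est_count, 3L)
  expect_error(estimate_cluster_count(100, 0, 10), class = "fq_calibration")
})

test_that("widefield spot detection counts a doublet as one, SR as two", {
  p <- small_params(seed = 51, n_nuclei = 1, her2_per_nucleus = 0,
                    cep17_per_nucleus = 0)
  bg <- make_background_field(64, 15, 8, 80, seed = 3)
  # two loci 150 nm apart plus three isolated reference loci
  em <- data.frame(x_nm = c(2000, 2150, 4000, 1000, 5000),
                   y_nm = c(2050, 2050, 4050, 4800, 1000),
                   photons = 12000)
  conv <- synthesize_frame(em, 130, 100, bg, read_noise_sd = 3, seed = 4)
  sig <- detect_spots_widefield(conv, radius_px = 4, pixel_size_nm = 100)
  expect_identical(nrow(sig), 4L)
  near_doublet <- which.min((sig$x_nm - 2075)^2 + (sig$y_nm - 2050)^2)
  expect_identical(sig$est_count[near_doublet], 2L)
  expect_true(all(sig$est_count[-near_doublet] == 1L))

  blank <- detect_spots_widefield(matrix(10, 32, 32), radius_px = 4)
  expect_identical(nrow(blank), 0L)

  # three isolated spots, each a single signal
  em3 <- data.frame(x_nm = c(1000, 3000, 5000), y_nm = c(1000, 3200, 5200),
                    photons = 12000)
  conv3 <- synthesize_frame(em3, 130, 100, bg, read_noise_sd = 3, seed = 5)
  sig3 <- detect_spots_widefield(conv3, radius_px = 4, pixel_size_nm = 100)
  expect_identical(nrow(sig3), 3L)
  expect_true(all(sig3$est_count == 1L))
})

test_that("signals are assigned to nuclei by centroid containment", {
  labels <- matrix(0L, 40, 40)
  labels[5:15, 5:15] <- 1L
  labels[25:35, 25:35] <- 2L
  nuclei <- structure(list(labels = labels,
                           nuclei = data.frame(id = 1:2,
                                               x_nm = c(1000, 3000),
                                               y_nm = c(1000, 3000),
                                               area_px = 121),
                           pixel_size_nm = 100), class = "nucleus_map")
  sig <- function(x, y, n, amb = FALSE)
    structure(data.frame(x_nm = x, y_nm = y, strength = 200 * n,
                         extent_nm = 40, est_count = as.integer(n),
                         ambiguous = amb), channel = "HER2", mode = "sr")
  # nucleus 1: 12 HER2 signals, 1 CEP17 signal (the amplified showcase)
  set.seed(2)
  her2 <- sig(runif(12, 600, 1400), runif(12, 600, 1400), rep(1, 12))
  cep17 <- sig(1050, 950, 1)
  counts <- count_per_nucleus(her2, cep17, nuclei)
  expect_equal(counts$H, c(12, 0))
  expect_equal(counts$C, c(1, 0))
  expect_identical(counts$cep17_countable, c(TRUE, FALSE))

  # a signal outside every nucleus is dropped and tallied
  out <- count_per_nucleus(sig(2000, 2000, 1), cep17[0, ], nuclei)
  expect_equal(sum(out$H), 0)
  expect_identical(attr(out, "n_outside"), 1L)

  # ambiguity propagates to the owning nucleus
  amb <- count_per_nucleus(her2, sig(1000, 1000, 5, TRUE), nuclei)
  expect_true(amb$cep17_ambiguous[1])
  expect_false(amb$cep17_countable[1])
})

test_that("sample-level metrics follow the eligibility rules", {
  counts <- data.frame(nucleus_id = 1:3, H = c(3, 5, 4),
                       her2_ambiguous = FALSE, C = c(2, 2, 0),
                       cep17_ambiguous = FALSE,
                       cep17_countable = c(TRUE, TRUE, FALSE))
  res <- summarize_counts(counts)
  expect_equal(res$ratio, 2)                    # (3+5)/(2+2)
  expect_identical(res$nuclei_with_her2, 3L)
  expect_equal(res$her2_signals, 12)
  expect_equal(res$her2_per_nucleus, 4)
  expect_identical(res$nuclei_with_cep17, 2L)
  expect_equal(res$cep17_signals, 4)

  single <- summarize_counts(data.frame(nucleus_id = 1, H = 3,
                                        her2_ambiguous = FALSE, C = 2,
                                        cep17_ambiguous = FALSE,
                                        cep17_countable = TRUE))
  expect_equal(single$ratio, 1.5)
  expect_equal(single$her2_per_nucleus, 3)
  expect_equal(single$cep17_per_nucleus, 2)

  # ambiguous nuclei leave the totals and live in their own tally
  counts$her2_ambiguous <- c(TRUE, FALSE, FALSE)
  res2 <- summarize_counts(counts)
  expect_identical(res2$nuclei_ambiguous_her2, 1L)
  expect_identical(res2$nuclei_with_her2, 2L)
  expect_equal(res2$her2_signals, 9)

  none <- summarize_counts(data.frame(nucleus_id = 1:2, H = c(4, 4),
                                      her2_ambiguous = FALSE, C = c(0, 3),
                                      cep17_ambiguous = c(FALSE, TRUE),
                                      cep17_countable = FALSE))
  expect_true(is.na(none$ratio))
  expect_match(none$ratio_reason, "countable")
  expect_error(summarize_counts(counts[0, ]), class = "fq_param")
})

test_that("counts and ratio are invariant to a global coordinate scaling", {
  p <- small_params(seed = 61, n_nuclei = 2)
  fld <- simulate_field(p)
  dm <- detection_threshold_model(p, seed = 5)
  out <- quantify_sr_field(fld, dm)
  locs <- out$localizations
  nuclei <- out$nuclei
  scale <- 2.5
  rescaled <- lapply(locs, function(l) {
    l$x_nm <- l$x_nm * scale; l$y_nm <- l$y_nm * scale; l
  })
  nuclei2 <- nuclei
  nuclei2$pixel_size_nm <- nuclei$pixel_size_nm * scale
  redo <- function(l, ch) annotate_signal_counts(
    cluster_localizations(l, 150 * scale, 3, ch),
    isolation_extent_nm = 120 * scale)
  c1 <- count_per_nucleus(redo(rescaled$HER2, "HER2"),
                          redo(rescaled$CEP17, "CEP17"), nuclei2)
  c0b <- count_per_nucleus(
    annotate_signal_counts(cluster_localizations(locs$HER2, 150, 3, "HER2"),
                           isolation_extent_nm = 120),
    annotate_signal_counts(cluster_localizations(locs$CEP17, 150, 3,
                                                 "CEP17"),
                           isolation_extent_nm = 120), nuclei)
  expect_equal(c1$H, c0b$H)
  expect_equal(c1$C, c0b$C)
  expect_equal(summarize_counts(c1)$ratio, summarize_counts(c0b)$ratio)
})
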