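test_that("widefield projection reduces frames as requested", {
  f1 <- matrix(1:16, 4); f2 <- matrix(16:1, 4)
  s <- fish_stack(array(c(f1, f1, f1), c(4, 4, 3)))
  expect_equal(widefield_projection(s), f1)
  s2 <- fish_stack(array(c(f1, f2), c(4, 4, 2)))
  expect_equal(widefield_projection(s2), (f1 + f2) / 2)
  expect_equal(widefield_projection(s2, "sum"), f1 + f2)
  expect_equal(widefield_projection(s2, "max"), pmax(f1, f2))
})

test_that("candidate detection finds isolated peaks and merges near ones", {
  expect_identical(nrow(detect_candidates(matrix(0, 9, 9), 0)), 0L)

  f <- psf_frame(25, 25, x_px = 12.5, y_px = 10.5, photons = 5000)
  pk <- detect_candidates(f, tau = 1)
  expect_identical(nrow(pk), 1L)
  expect_identical(c(pk$row, pk$col), c(11L, 13L))

  # 3 x 3 grid of well-separated spots
  centres <- expand.grid(x = c(5.5, 15.5, 25.5), y = c(5.5, 15.5, 25.5))
  em <- data.frame(x_nm = centres$x * 100, y_nm = centres$y * 100,
                   photons = 3000)
  grid <- synthesize_frame(em, 130, 100, matrix(0, 31, 31), poisson = FALSE)
  expect_identical(nrow(detect_candidates(grid, 5)), 9L)

  # two maxima 1 px apart collapse onto the brighter
  m <- matrix(0, 9, 9)
  m[4, 4] <- 10; m[4, 5] <- 12
  got <- detect_candidates(m, 1, min_separation_px = 2)
  expect_identical(nrow(got), 1L)
  expect_identical(got$col, 5L)
})

test_that("noiseless Gaussian fits recover the centre to machine precision", {
  # fixture sampled from the fitter's own model (point-sampled Gaussian)
  xs <- seq_len(21) - 0.5
  g <- 40 + 900 * exp(-(outer((xs - 10.5)^2, (xs - 12.2)^2, "+")) /
                        (2 * 1.3^2))
  rec <- fit_gaussian_spot(g, c(11, 12), psf_sigma_nm = 130)
  expect_equal(rec$x_nm / 100, 12.2, tolerance = 1e-6)
  expect_equal(rec$y_nm / 100, 10.5, tolerance = 1e-6)
  expect_equal(rec$sigma_nm / 100, 1.3, tolerance = 1e-5)
  expect_equal(rec$background, 40, tolerance = 1e-4)

  flat <- fit_gaussian_spot(matrix(7, 21, 21), c(11, 11))
  expect_identical(nrow(flat), 0L)
  expect_match(attr(flat, "rejection"), "amplitude|convergence")
})

test_that("the spot fitter agrees with an independent least-squares solver", {
  skip_if_not_installed("minpack.lm")
  set.seed(77)
  em <- data.frame(x_nm = 740, y_nm = 760, photons = 5000)
  f <- synthesize_frame(em, 130, 100, matrix(60, 15, 15), read_noise_sd = 3)
  got <- fit_gaussian_spot(f, c(8, 8), psf_sigma_nm = 130)
  win <- f[5:11, 5:11]
  df <- data.frame(v = as.vector(win),
                   cx = rep(4:10 + 0.5, each = 7),
                   cy = rep(4:10 + 0.5, times = 7))
  ref <- minpack.lm::nlsLM(
    v ~ b + A * exp(-((cx - x0)^2 + (cy - y0)^2) / (2 * s^2)), data = df,
    start = list(A = max(win) - min(win), x0 = 7.5, y0 = 7.5, s = 1.3,
                 b = min(win)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(ref)
  expect_equal(got$x_nm / 100, unname(cf["x0"]), tolerance = 1e-5)
  expect_equal(got$y_nm / 100, unname(cf["y0"]), tolerance = 1e-5)
  expect_equal(got$sigma_nm / 100, unname(cf["s"]), tolerance = 1e-4)
  expect_equal(got$background, unname(cf["b"]), tolerance = 1e-3)
})

test_that("localization error shrinks as sqrt(photons)", {
  set.seed(99)
  bg <- matrix(50, 15, 15)
  rmse <- vapply(c(5000, 20000), function(photons) {
    err2 <- vapply(1:150, function(k) {
      em <- data.frame(x_nm = 730, y_nm = 770, photons = photons)
      f <- synthesize_frame(em, 130, 100, bg, read_noise_sd = 3)
      rec <- fit_gaussian_spot(f, c(8, 8), psf_sigma_nm = 130)
      if (nrow(rec) == 0) return(NA_real_)
      (rec$x_nm - 730)^2 + (rec$y_nm - 770)^2
    }, numeric(1))
    sqrt(mean(err2, na.rm = TRUE))
  }, numeric(1))
  expect_lt(rmse[1], 20)
  expect_gt(rmse[1] / rmse[2], 1.5)
  expect_lt(rmse[1] / rmse[2], 2.5)
})

test_that("localizing a stack collects per-frame fits deterministically", {
  z <- fish_stack(array(0, c(16, 16, 4)))
  got <- localize_stack(z, tau = 5, preprocess = "none")
  expect_identical(nrow(got), 0L)

  # one immobile locus blinking through a short acquisition
  p <- small_params(seed = 21, n_nuclei = 1, her2_per_nucleus = 1,
                    cep17_per_nucleus = 0, n_frames_signal = 300)
  fld <- simulate_field(p)
  dm <- detection_threshold_model(p, seed = 5)
  locs <- localize_stack(fld$her2, tau_model = dm)
  locs2 <- localize_stack(fld$her2, tau_model = dm)
  expect_identical(locs, locs2)
  ev <- fld$truth$events$HER2
  on_frames <- unique(ev$frame)
  sig <- fld$truth$signals
  d <- sqrt((locs$x_nm - mean(ev$x_px * 100))^2 +
              (locs$y_nm - mean(ev$y_px * 100))^2)
  # >= 90% of on-frames yield a localization near the locus
  hit_frames <- unique(locs$frame[d < 250])
  expect_gte(length(intersect(on_frames, hit_frames)),
             0.9 * length(on_frames))
  expect_true(all(locs$frame >= 0 & locs$frame < 300))
})

test_that("rendering conserves counts and sharpens doublets", {
  one <- data.frame(frame = 0L, x_nm = 1000, y_nm = 1000, sigma_nm = 130,
                    photons = 1000, background = 0, uncertainty_nm = 10)
  img <- render_superres(one, 20, "histogram", field_nm = c(2000, 2000))
  expect_equal(img[51, 51], 1)
  expect_equal(sum(img), 1)

  set.seed(17)
  n <- 500
  tab <- data.frame(frame = 0L, x_nm = runif(n, 0, 3000),
                    y_nm = runif(n, 0, 3000), sigma_nm = 130,
                    photons = 1000, background = 0,
                    uncertainty_nm = runif(n, 5, 30))
  expect_equal(sum(render_superres(tab, 20, "histogram",
                                   field_nm = c(3100, 3100))), n)
  gs <- render_superres(tab, 20, "gaussian", field_nm = c(3100, 3100))
  expect_lt(abs(sum(gs) - n) / n, 0.01)

  # two loci 150 nm apart: distinct at 20 nm rendering, merged at 200 nm
  loc2 <- data.frame(frame = 0L,
                     x_nm = rnorm(400, rep(c(1000, 1150), 200), 8),
                     y_nm = rnorm(400, 1000, 8), sigma_nm = 130,
                     photons = 1000, background = 0, uncertainty_nm = 8)
  fine <- render_superres(loc2, 20, "histogram", field_nm = c(2000, 2000))
  comp <- function(img) {
    bw <- EBImage::bwlabel(img > max(img) / 5)
    max(bw)
  }
  expect_identical(comp(fine), 2L)
  coarse <- render_superres(loc2, 200, "histogram", field_nm = c(2000, 2000))
  expect_identical(comp(coarse), 1L)
})

test_that("rendering rejects bad parameters and empty-table corners", {
  expect_error(render_superres(NULL, 0), class = "fq_param")
  expect_error(render_superres(NULL, 20), class = "fq_param")
  z <- render_superres(as_localizations(NULL), 20, field_nm = c(400, 400))
  expect_equal(z, matrix(0, 20, 20))
})
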