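test_that("rolling-ball background equals the brute-force opening oracle", {
  # the canonical spike fixture
  img <- matrix(10, 8, 8)
  img[4, 5] <- 110
  bg <- rolling_ball_background(img, 2)
  expect_equal(bg, matrix(10, 8, 8))
  expect_equal(bg, brute_disk_opening(img, 2))
  # random images, several radii
  set.seed(71)
  for (rep in 1:20) {
    m <- matrix(sample(0:100, 16 * 16, TRUE), 16)
    for (r in 1:3)
      expect_equal(rolling_ball_background(m, r), brute_disk_opening(m, r))
  }
})

test_that("opening is idempotent and bounded by the image", {
  set.seed(72)
  for (rep in 1:5) {
    m <- matrix(rpois(20 * 20, 50) + 0, 20)
    bg <- rolling_ball_background(m, 3)
    expect_true(all(bg <= m))
    expect_equal(rolling_ball_background(bg, 3), bg)
  }
  c5 <- matrix(5, 10, 10)
  expect_equal(rolling_ball_background(c5, 4), c5)
  expect_error(rolling_ball_background(c5, 0), class = "fq_param")
  expect_error(rolling_ball_background(c5, 11), class = "fq_param")
})

test_that("background subtraction flattens floors and keeps spikes", {
  img <- matrix(10, 8, 8)
  img[4, 5] <- 110
  out <- subtract_background(img, 2)
  expect_equal(out[4, 5], 100)
  expect_equal(sum(out), 100)
  expect_equal(subtract_background(matrix(7, 9, 9), 3), matrix(0, 9, 9))
})

test_that("spot amplitudes survive subtraction on a smooth gradient", {
  h <- 40
  grad <- outer(seq(0, 30, length.out = h), seq(0, 20, length.out = h), "+")
  spots <- data.frame(x_nm = c(1050, 2550), y_nm = c(1250, 3050),
                      photons = c(3000, 5000))
  img <- synthesize_frame(spots, psf_sigma_nm = 130, pixel_size_nm = 100,
                          background_field = grad, poisson = FALSE)
  out <- subtract_background(img, 8)
  clean <- img - grad
  pk <- cbind(c(13, 31), c(11, 26))   # (row, col) of the two spots
  for (k in 1:2) {
    got <- out[pk[k, 1], pk[k, 2]]
    want <- clean[pk[k, 1], pk[k, 2]]
    expect_lt(abs(got - want) / want, 0.05)
  }
})

test_that("optimal threshold separates signal from floor and obeys ties", {
  img <- matrix(10, 10, 10)
  img[3:4, 6] <- 100
  mask <- img == 100
  # any tau in (10, 100] is perfect; the smallest unique value wins
  expect_equal(optimal_threshold(img, mask), 10)
  expect_error(optimal_threshold(img, img > 1e9), class = "fq_degenerate")
  expect_error(optimal_threshold(matrix(5, 4, 4), matrix(TRUE, 4, 4)),
               class = "fq_degenerate")
})

test_that("optimal threshold equals the exhaustive F1 scan", {
  set.seed(77)
  bg <- make_background_field(32, 15, 4, 60)
  em <- data.frame(x_nm = c(800, 2000, 2600), y_nm = c(900, 1500, 2400),
                   photons = 2000)
  contrib <- synthesize_frame(em, 130, 100, matrix(0, 32, 32),
                              poisson = FALSE)
  img <- synthesize_frame(em, 130, 100, bg, read_noise_sd = 3)
  mask <- contrib > 0.2 * max(contrib)
  got <- optimal_threshold(img, mask)
  f1 <- function(tau) {
    pred <- img > tau
    tp <- sum(pred & mask)
    2 * tp / (2 * tp + sum(pred & !mask) + sum(!pred & mask))
  }
  cand <- sort(unique(as.vector(img)))
  scores <- vapply(cand, f1, numeric(1))
  expect_equal(got, cand[which.max(scores)])
  expect_equal(f1(got), max(scores))
})

test_that("threshold regression recovers an exact plane and the OLS oracle", {
  cal <- data.frame(mean = c(10, 20, 30, 15, 42), sd = c(3, 9, 4, 7, 6))
  cal$tau_opt <- 2 * cal$mean + 3 * cal$sd + 5
  m <- fit_threshold_model(cal)
  expect_equal(m$coef_mean, 2, tolerance = 1e-10)
  expect_equal(m$coef_sd, 3, tolerance = 1e-10)
  expect_equal(m$intercept, 5, tolerance = 1e-10)
  expect_equal(m$r, 1)

  set.seed(41)
  noisy <- data.frame(mean = runif(50, 5, 50), sd = runif(50, 1, 12))
  noisy$tau_opt <- 2 * noisy$mean + 3 * noisy$sd + 5 + rnorm(50)
  m2 <- fit_threshold_model(noisy)
  beta <- normal_equations_fit(noisy)
  expect_equal(m2$intercept, beta[1], tolerance = 1e-8)
  expect_equal(m2$coef_mean, beta[2], tolerance = 1e-8)
  expect_equal(m2$coef_sd, beta[3], tolerance = 1e-8)
  # coefficients land within 3 standard errors of the truth
  fit <- lm(tau_opt ~ mean + sd, data = noisy)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - c(5, 2, 3)) < 3 * se))

  bad <- data.frame(mean = 1:5, sd = 2 * (1:5))
  bad$tau_opt <- bad$mean
  expect_error(fit_threshold_model(bad), class = "fq_rank")
  expect_error(fit_threshold_model(cal[1:2, ]), class = "fq_param")
})

test_that("threshold prediction and application behave as specified", {
  m <- structure(list(coef_mean = 0, coef_sd = 0, intercept = 1490, r = 1,
                      n_calibration = 3, residual_q95 = 0),
                 class = "threshold_model")
  expect_equal(estimate_threshold(m, matrix(runif(100), 10)), 1490)
  m2 <- structure(list(coef_mean = 1, coef_sd = 0, intercept = 0, r = 1,
                       n_calibration = 3, residual_q95 = 0),
                  class = "threshold_model")
  expect_equal(estimate_threshold(m2, matrix(42, 5, 5)), 42)

  img <- matrix(10, 4, 4); img[2, 2] <- 60
  expect_equal(apply_threshold(img, 10), matrix(c(0, 60)[1 + (img > 10)], 4))
  expect_equal(apply_threshold(img, 50)[2, 2], 60)
  expect_equal(sum(apply_threshold(img, 50)), 60)
  z <- matrix(c(0, 2, 0, 3), 2)
  expect_equal(apply_threshold(z, 0), z)   # strict >: zeros stay zero
  expect_error(apply_threshold(img, -1), class = "fq_param")
})

test_that("calibration residuals bound the round-trip prediction error", {
  cal <- calibrate_threshold_model(20, small_params(), seed = 5)
  q95 <- cal$model$residual_q95
  preds <- cal$model$intercept + cal$model$coef_mean * cal$calibration$mean +
    cal$model$coef_sd * cal$calibration$sd
  err <- abs(preds - cal$calibration$tau_opt)
  expect_lte(sort(err)[ceiling(0.95 * length(err))], q95 + 1e-9)
})
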