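test_that("background field honours the zero-amplitude and seed contracts", {
  expect_equal(make_background_field(16, 0, 8, 50), matrix(50, 16, 16))
  a <- make_background_field(64, 30, 8, 100, seed = 1)
  b <- make_background_field(64, 30, 8, 100, seed = 1)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_error(make_background_field(0, 1, 2, 3), class = "fq_param")
  expect_error(make_background_field(16, -1, 2, 3), class = "fq_param")
})

test_that("background field mean matches the clipped-normal closed form", {
  # per-pixel value is max(0, offset + amplitude * Z), Z standard normal:
  # E = mu * pnorm(mu/s) + s * dnorm(mu/s)
  mu <- 20; s <- 30
  want <- mu * pnorm(mu / s) + s * dnorm(mu / s)
  means <- vapply(1:100, function(seed)
    mean(make_background_field(32, s, 4, mu, seed = seed)), numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - want), 3 * se)
})

test_that("blinking traces follow the Bernoulli/Poisson model", {
  tr <- simulate_blinking_trace(100, p_on = 1e-12, seed = 4)
  expect_true(all(tr == 0))
  expect_error(simulate_blinking_trace(100, p_on = 0), class = "fq_param")
  expect_error(simulate_blinking_trace(100, p_on = 1), class = "fq_param")
  expect_error(simulate_blinking_trace(0), class = "fq_param")

  set.seed(8)
  on_total <- sum(vapply(1:200, function(k)
    sum(simulate_blinking_trace(5000, 0.005, 1500) > 0), numeric(1)))
  n <- 5000 * 200; p <- 0.005
  expect_lt(abs(on_total - n * p), 3 * sqrt(n * p * (1 - p)))

  # acquisition defaults carried into the simulator
  dp <- sim_params()
  expect_identical(dp$n_frames_signal, 5000)
  expect_identical(dp$n_frames_dapi, 1000)
})

test_that("frame synthesis conserves photons and positions", {
  zero <- synthesize_frame(NULL, background_field = matrix(0, 16, 16),
                           poisson = FALSE)
  expect_equal(zero, matrix(0, 16, 16))

  f <- psf_frame(32, 32, x_px = 10.5, y_px = 12.5, photons = 1e6)
  expect_lt(abs(sum(f) - 1e6) / 1e6, 0.01)
  cx <- sum(t(f) * (seq_len(32) - 0.5)) / sum(f)
  cy <- sum(f * (seq_len(32) - 0.5)) / sum(f)
  expect_lt(abs(cx - 10.5), 0.01)
  expect_lt(abs(cy - 12.5), 0.01)

  expect_error(synthesize_frame(data.frame(x_nm = -5, y_nm = 10,
                                           photons = 10),
                                background_field = matrix(0, 16, 16)),
               class = "fq_range")
})

test_that("a 150-nm doublet is unresolved in the rendered frame", {
  em <- data.frame(x_nm = c(1000, 1150), y_nm = 1050, photons = 5000)
  f <- synthesize_frame(em, psf_sigma_nm = 130, pixel_size_nm = 100,
                        background_field = matrix(0, 21, 21),
                        poisson = FALSE)
  pk <- detect_candidates(f, tau = max(f) / 20, min_separation_px = 0)
  expect_identical(nrow(pk), 1L)
  # the same doublet evaluated on a fine grid has a single maximum too
  xs <- seq(800, 1350, by = 5)
  prof <- rowSums(vapply(c(1000, 1150), function(mu)
    dnorm(xs, mu, 130), numeric(length(xs))))
  expect_identical(sum(diff(sign(diff(prof))) == -2), 1L)
})

test_that("simulate_field honours counts, shapes and determinism", {
  p0 <- small_params(seed = 2, her2_per_nucleus = 0, cep17_per_nucleus = 0)
  f0 <- simulate_field(p0)
  expect_identical(nrow(f0$truth$signals), 0L)
  expect_identical(dim(f0$her2$data), c(64L, 64L, 400L))
  expect_identical(dim(f0$dapi$data), c(64L, 64L, 150L))

  p <- small_params(seed = 7, n_nuclei = 3, her2_per_nucleus = 2,
                    cep17_per_nucleus = 2)
  f <- simulate_field(p)
  expect_equal(f$truth$per_nucleus$H, rep(2, 3))
  expect_equal(f$truth$per_nucleus$C, rep(2, 3))
  expect_equal(nrow(f$truth$emitters), 12 * p$emitters_per_signal)

  g <- simulate_field(p)
  expect_identical(f$her2$data, g$her2$data)
  expect_identical(f$cep17$data, g$cep17$data)
  expect_identical(f$dapi$data, g$dapi$data)
  expect_identical(f$truth$signals, g$truth$signals)
})

test_that("per-nucleus truth counts equal the signal records per channel", {
  f <- simulate_field(small_params(seed = 12, n_nuclei = 4,
                                   her2_per_nucleus = 3,
                                   cluster_fraction = 0.5))
  sig <- f$truth$signals
  for (i in f$truth$per_nucleus$nucleus_id) {
    expect_identical(sum(sig$channel == "HER2" & sig$nucleus_id == i),
                     f$truth$per_nucleus$H[f$truth$per_nucleus$nucleus_id == i])
    expect_identical(sum(sig$channel == "CEP17" & sig$nucleus_id == i),
                     f$truth$per_nucleus$C[f$truth$per_nucleus$nucleus_id == i])
  }
  # cluster nuclei gained one locus of > 4 co-located signals
  expect_identical(sum(f$truth$per_nucleus$has_cluster), 2L)
  expect_true(all(f$truth$per_nucleus$H[f$truth$per_nucleus$has_cluster] ==
                    3 + 6))
})

test_that("every locus centroid lies inside its nucleus mask", {
  f <- simulate_field(small_params(seed = 3))
  mask <- f$truth$nucleus_mask
  sig <- f$truth$signals
  px <- f$her2$pixel_size_nm
  labs <- mask[cbind(floor(sig$y_nm / px) + 1, floor(sig$x_nm / px) + 1)]
  expect_equal(labs, sig$nucleus_id)
})

test_that("the photon budget matches expectation over repeated seeds", {
  total <- numeric(20)
  expected <- numeric(20)
  for (s in 1:20) {
    p <- small_params(seed = 400 + s, n_nuclei = 3)
    f <- simulate_field(p)
    total[s] <- sum(f$truth$events$HER2$photons)
    n_sig <- sum(f$truth$signals$channel == "HER2")
    expected[s] <- n_sig * p$emitters_per_signal * p$n_frames_signal *
      p$p_on * p$mean_photons
  }
  # Binomial on-frames x Poisson photon load: var per emitter-trace ~
  # T p (1-p) mu^2 + T p mu
  p <- small_params(n_nuclei = 3)
  n_em <- 6 * p$emitters_per_signal
  v <- n_em * (p$n_frames_signal * p$p_on * (1 - p$p_on) * p$mean_photons^2 +
                 p$n_frames_signal * p$p_on * p$mean_photons)
  z <- (mean(total) - mean(expected)) / sqrt(v / 20)
  expect_lt(abs(z), 3)
})
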