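test_that("interval sampler is seeded, matches the model CDF and its mean", {
  prm <- ref_params()
  expect_identical(sample_intervals(prm, 100, seed = 3),
                   sample_intervals(prm, 100, seed = 3))
  # analytic mean A/a + (1-A)/(p b) = 11.0 min
  x <- sample_intervals(prm, 1e5, seed = 2)
  expect_equal(mean(x), 11.0, tolerance = 0.02)
  # p -> 1: indistinguishable from Exp(1)
  x1 <- sample_intervals(interval_params(0.999999, 1, 0.1), 1e4, seed = 4)
  ks <- suppressWarnings(ks.test(x1, pexp, rate = 1))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_intervals(interval_params(0.5, 0.1, 1), 10, seed = 1),
               "mixture")
})

test_that("empirical CDF of sampled intervals converges to interval_cdf", {
  set.seed(99)
  for (rep in 1:5) {
    prm <- random_valid_params()
    x <- sample_intervals(prm, 1e4, seed = 100 + rep)
    ks_dist <- max(abs(ecdf(x)(sort(x)) - interval_cdf(sort(x), prm)))
    expect_lt(ks_dist, 0.02)
  }
})

test_that("simulated timelines respect duration, order and the renewal rate", {
  prm <- ref_params()
  tl <- simulate_timeline(prm, duration = 120, seed = 11)
  expect_s3_class(tl, "egg_timeline")
  expect_true(all(tl$event_times >= 0 & tl$event_times <= 120))
  expect_true(all(diff(tl$event_times) > 0))
  expect_identical(simulate_timeline(prm, 120, seed = 11)$event_times,
                   tl$event_times)
  # duration shorter than any plausible first interval
  tiny <- simulate_timeline(interval_params(0.999, 0.001, 0.001), 1e-6, seed = 1)
  expect_length(tiny$event_times, 0)
  # mean event count ~ duration / mean_interval = 120 / 11 at first order;
  # the hyperexponential renewal process carries an inspection-paradox
  # correction of (CV^2 - 1)/2 counts (CV^2 = var/mean^2 of the interval law)
  counts <- vapply(1:300, function(s)
    length(simulate_timeline(prm, 120, seed = s)$event_times), numeric(1))
  expect_equal(mean(counts), 120 / 11, tolerance = 0.15)
  w <- ttcal:::mixture_weights(prm)
  ex2 <- 2 * (w$A / prm$a^2 + w$B / (prm$p * prm$b)^2)
  cv2 <- (ex2 - 11^2) / 11^2
  expect_equal(mean(counts), 120 / 11 + (cv2 - 1) / 2, tolerance = 0.07)
})

test_that("gating-curve generators reproduce the Boltzmann and are seeded", {
  act <- boltzmann_params(-40, 5, "activation")
  clean <- simulate_peak_conductance(act, act_grid, noise_sd = 0, n_cells = 2,
                                     seed = 1)
  expect_equal(clean[[1]]$g, boltzmann(act_grid, act))
  expect_equal(simulate_peak_conductance(act, -40, 0, 1, seed = 1)[[1]]$g, 0.5)
  noisy <- simulate_peak_conductance(act, act_grid, noise_sd = 0.02,
                                     n_cells = 10, seed = 8)
  mean_curve <- colMeans(do.call(rbind, lapply(noisy, `[[`, "g")))
  expect_true(all(abs(mean_curve - boltzmann(act_grid, act)) < 0.02))
  expect_error(simulate_peak_conductance(act, numeric(0), 0, 1, seed = 1),
               "non-empty")

  inact <- boltzmann_params(-60, 5, "inactivation")
  icurves <- simulate_inactivation_curve(inact, inact_grid, noise_sd = 0,
                                         n_cells = 1, seed = 1)
  g <- icurves[[1]]$g
  expect_equal(g[inact_grid == -60], 0.5)
  expect_true(all(diff(g) <= 0))                       # monotone decreasing
  expect_equal(boltzmann(-300, inact), 1, tolerance = 1e-6)  # full availability
  expect_error(simulate_inactivation_curve(act, inact_grid, 0, 1, seed = 1),
               "inactivation")
})

test_that("fluorescence generator builds baseline + drift + transients", {
  # no transients, no noise: exactly affine
  tr <- simulate_fluorescence(bleach_slope = -0.05, f0 = 100, bg = 10,
                              noise_sd = 0, duration = 900, rate = 0.5)
  expect_length(tr$roi, 450)                           # 900 s x 0.5 Hz
  t <- (seq_along(tr$roi) - 1) * 2
  expect_equal(tr$roi, 100 - 0.05 * t)
  expect_equal(tr$background, rep(10, 450))
  # one transient: max at the first sample at/after onset
  tr1 <- simulate_fluorescence(transient_times = 101, amplitude = 30,
                               decay_tau = 5, bleach_slope = 0, f0 = 100,
                               noise_sd = 0)
  expect_equal(which.max(tr1$roi), min(which(t >= 101)))
  expect_error(simulate_fluorescence(transient_times = 1000, duration = 900),
               "within")
  n1 <- simulate_fluorescence(noise_sd = 2, seed = 5)
  expect_identical(n1$roi, simulate_fluorescence(noise_sd = 2, seed = 5)$roi)
})

test_that("stage sampler is a seeded multinomial over seven categories", {
  one_hot <- c(0, 0, 1, 0, 0, 0, 0)
  d <- sample_stages(one_hot, 25, seed = 1)
  expect_equal(as.integer(d), c(0, 0, 25, 0, 0, 0, 0))
  expect_equal(sum(sample_stages(rep(1 / 7, 7), 0, seed = 1)), 0L)
  d7 <- sample_stages(rep(1 / 7, 7), 7000, seed = 9)
  # each count within 4 sd of 1000; sd = sqrt(n p (1-p)) ~ 29.3
  expect_true(all(abs(as.integer(d7) - 1000) < 4 * sqrt(7000 * (1/7) * (6/7))))
  expect_error(sample_stages(c(-0.1, rep(1.1 / 6, 6)), 10, seed = 1),
               "non-negative")
  expect_error(sample_stages(rep(0.1, 7), 10, seed = 1), "sum")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(sample_intervals(ref_params(), 100, seed = 5))
  invisible(simulate_fluorescence(noise_sd = 1, seed = 5))
  expect_identical(.Random.seed, before)
})
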