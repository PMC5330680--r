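test_that("interval CDF matches hand-evaluated values and limits", {
  prm <- ref_params()
  # A = 0.5*0.9/0.95, B = 1*0.5/0.95; F(1) = 1 - (A e^-1 + B e^-0.05)
  A <- 0.5 * (1 - 0.1) / (1 - 0.05)
  B <- 1 * 0.5 / (1 - 0.05)
  expect_equal(A, 0.473684, tolerance = 1e-6)
  expect_equal(interval_cdf(0, prm), 0)
  expect_equal(interval_cdf(1, prm), 1 - (A * exp(-1) + B * exp(-0.05)))
  expect_equal(interval_cdf(1, prm), 0.3251, tolerance = 1e-4)
  # p -> 1 collapses to a single exponential
  near1 <- interval_params(1 - 1e-9, 1, 0.1)
  x <- c(0.1, 1, 5, 20)
  expect_equal(interval_cdf(x, near1), 1 - exp(-x), tolerance = 1e-6)
  expect_error(interval_cdf(-1, prm), "0")
  expect_error(interval_params(0.5, 0.05, 0.1), "p\\*b")
})

test_that("interval PDF integrates to 1, is nonnegative, equals dF/dx", {
  prm <- ref_params()
  expect_equal(interval_pdf(0, prm), 0.5)  # A*a + B*p*b = 0.473684 + 0.026316
  q <- integrate(function(x) interval_pdf(x, prm), 0, Inf, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  set.seed(42)
  for (rep in 1:5) {
    prm_i <- random_valid_params()
    grid <- seq(0.05, 40, length.out = 100)
    h <- 1e-5
    num <- (interval_cdf(grid + h, prm_i) - interval_cdf(grid - h, prm_i)) / (2 * h)
    expect_equal(interval_pdf(grid, prm_i), num, tolerance = 1e-6)
    expect_true(all(interval_pdf(grid, prm_i) >= 0))
  }
})

test_that("mixture weights sum to one and CDF is a proper nondecreasing CDF", {
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(1, 0.01, 0.99)
    a <- runif(1, 0.01, 50)
    b <- runif(1, 0.01, 50)
    if (abs(a - p * b) < 1e-8) next
    prm <- interval_params(p, a, b)
    w <- ttcal:::mixture_weights(prm)
    expect_equal(w$A + w$B, 1, tolerance = 1e-12)
  }
  for (rep in 1:10) {
    prm <- random_valid_params()
    Fx <- interval_cdf(seq(0, 200, length.out = 2000), prm)
    expect_true(all(diff(Fx) >= -1e-12))
    expect_true(all(Fx >= 0 & Fx <= 1))
    expect_lt(abs(interval_cdf(1e5, prm) - 1), 1e-6)
  }
})

test_that("time constants and mean interval are the analytic values", {
  expect_equal(time_constants(ref_params()),
               c(tau_fast = 1, tau_slow = 20))
  expect_equal(time_constants(interval_params(0.25, 2, 0.2)),
               c(tau_fast = 0.5, tau_slow = 20))
  expect_equal(mean_interval(ref_params()), 11.0)
  # p -> 1: mean -> 1/a
  expect_equal(mean_interval(interval_params(1 - 1e-10, 2, 0.1)), 0.5,
               tolerance = 1e-6)
})

test_that("quantile function inverts the CDF", {
  prm <- ref_params()
  q <- c(0, 0.1, 0.5, 0.9, 0.999)
  x <- interval_quantile(q, prm)
  expect_equal(interval_cdf(x, prm), q, tolerance = 1e-9)
})

test_that("fitting exact model quantiles recovers the parameters", {
  prm <- ref_params()
  n <- 200
  pp <- (seq_len(n) - 0.5) / n
  x <- interval_quantile(pp, prm)
  fit <- fit_intervals(x)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.5, 1, 0.1), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  # CIs bracket the point estimates
  expect_true(all(fit$ci95[, 1] <= coef(fit) & coef(fit) <= fit$ci95[, 2]))
})

test_that("parameters are recovered from sampled intervals within 15%", {
  prm <- ref_params()
  x <- sample_intervals(prm, 1000, seed = 7)
  fit <- fit_intervals(x)
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est[["p"]] - 0.5) / 0.5, 0.15)
  expect_lt(abs(est[["a"]] - 1) / 1, 0.15)
  expect_lt(abs(est[["b"]] - 0.1) / 0.1, 0.15)
})

test_that("single-exponential data collapses the model onto a ridge", {
  set.seed(3)
  x <- rexp(500, rate = 0.5)
  fit <- fit_intervals(x)
  expect_true(fit$converged)
  est <- coef(fit)
  # the ridge: rates coincide, or one component's weight vanishes
  w <- ttcal:::mixture_weights(fit$params)
  collapsed <- abs(est[["a"]] - est[["p"]] * est[["b"]]) / est[["a"]] < 0.25 ||
    est[["p"]] > 0.95 || min(w$A, w$B) < 0.1
  expect_true(collapsed)
  # and the fitted law is indistinguishable from the single exponential
  xx <- seq(0.01, 20, length.out = 500)
  expect_lt(max(abs(interval_cdf(xx, fit$params) - pexp(xx, 0.5))), 0.05)
})

test_that("fit input validation and method surface behave", {
  expect_error(fit_intervals(1:5), "at least 10")
  expect_error(fit_intervals(c(rep(1, 10), -2)), "> 0")
  x <- sample_intervals(ref_params(), 300, seed = 5)
  fit <- fit_intervals(x)
  expect_equal(length(residuals(fit)), 300)
  expect_equal(predict(fit, newdata = 0), 0)
  sims <- simulate(fit, nsim = 50, seed = 1)
  expect_length(sims, 50)
  expect_output(print(fit), "tau_fast")
})

test_that("component canonicalisation preserves the distribution", {
  # parameters with a < p*b describe the same mixture with swapped labels
  prm <- interval_params(p = 0.4, a = 0.05, b = 1)   # a=0.05 < p*b=0.4
  can <- ttcal:::canonicalise_params(prm)
  expect_gt(can$a, can$p * can$b)
  x <- c(0.1, 0.5, 1, 5, 20, 60)
  expect_equal(interval_cdf(x, can), interval_cdf(x, prm), tolerance = 1e-12)
})
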