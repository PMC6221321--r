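test_that("local quadratic fit matches an lm-based oracle at single points", {
  set.seed(11)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  for (rep_i in 1:20) {
    y <- rnorm(15, sd = 0.3) + 0.2 * tt
    h <- sample(c(3.2, 4.4, 5.6, 8), 1)
    t0 <- runif(1, 0, 8)
    fit <- fit_local_quadratic(tt, y, h, eval_times = t0)
    expect_equal(fit$fitted, naive_local_fit(tt, y, h, t0), tolerance = 1e-9)
  }
})

test_that("exactly quadratic data are reproduced exactly at any bandwidth", {
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  set.seed(5)
  for (i in 1:10) {
    b <- rnorm(3)
    y <- b[1] + b[2] * tt + b[3] * tt^2
    fit <- fit_local_quadratic(tt, y, bandwidth = 8)
    truth <- b[1] + b[2] * fit$eval_times + b[3] * fit$eval_times^2
    expect_equal(fit$fitted, truth, tolerance = 1e-8)
  }
})

test_that("constant input gives a flat fit with zero half-widths", {
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  fit <- fit_local_quadratic(tt, rep(3.5, 15), bandwidth = 8)
  expect_equal(fit$fitted, rep(3.5, length(fit$eval_times)), tolerance = 1e-10)
  expect_equal(unname(simultaneous_band(fit, 0.05)),
               rep(0, length(fit$eval_times)))
})

test_that("LOO-CV bandwidth selection matches explicit refitting", {
  set.seed(21)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  cands <- c(3.2, 4.4, 5.6, 6.8, 8)
  for (i in 1:10) {
    y <- rnorm(15, sd = 0.3) + 0.3 * tt - 0.03 * tt^2
    cv_oracle <- vapply(cands, function(h) naive_loocv(tt, y, h), numeric(1))
    expect_equal(select_bandwidth_loocv(tt, y, cands),
                 cands[which.min(cv_oracle)])
  }
})

test_that("near-quadratic data select the largest bandwidth", {
  set.seed(3)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  picks <- replicate(60, {
    y <- 1 + 0.5 * tt - 0.05 * tt^2 + rnorm(15, sd = 0.01)
    select_bandwidth_loocv(tt, y, c(3.2, 4.4, 5.6, 6.8, 8))
  })
  # bias-free signal: the widest bandwidths dominate (exact ties between
  # near-identical CV errors occasionally favour a middle candidate)
  expect_equal(median(picks), 8)
  expect_gte(mean(picks >= 5.6), 0.7)
})

test_that("a single candidate bandwidth is returned unchanged", {
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  expect_equal(select_bandwidth_loocv(tt, rnorm(15), 4.4), 4.4)
})

test_that("a sharp early spike selects a smaller bandwidth than a flat course", {
  set.seed(17)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  cands <- c(3.2, 4.4, 5.6, 6.8, 8)
  spike <- vapply(1:50, function(i) {
    y <- 1.4 * tt * exp(1 - tt) + rnorm(15, sd = 0.1)
    select_bandwidth_loocv(tt, y, cands)
  }, numeric(1))
  flat <- vapply(1:50, function(i) {
    y <- rnorm(15, sd = 0.1)
    select_bandwidth_loocv(tt, y, cands)
  }, numeric(1))
  expect_lt(median(spike), median(flat))
})

test_that("tube-formula critical value reduces to the t quantile at one point", {
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  set.seed(2)
  y <- rnorm(15)
  fit <- fit_local_quadratic(tt, y, 8, eval_times = 4)
  expect_equal(fit$kappa0, 0)
  hw <- simultaneous_band(fit, 0.05)
  expect_equal(hw, qt(0.975, fit$df) * fit$se_fitted, tolerance = 1e-6)
})

test_that("stricter levels widen the simultaneous band", {
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  set.seed(4)
  fit <- fit_local_quadratic(tt, rnorm(15), 5.6)
  expect_true(all(simultaneous_band(fit, 0.01) > simultaneous_band(fit, 0.05)))
})

test_that("simultaneous band contains the pointwise band at every grid point", {
  set.seed(6)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  for (i in 1:10) {
    fit <- fit_local_quadratic(tt, rnorm(15, sd = 0.5), sample(c(3.2, 8), 1))
    pw <- qt(0.975, fit$df) * fit$se_fitted
    expect_true(all(simultaneous_band(fit, 0.05) >= pw - 1e-12))
  }
})

test_that("fitted curve tracks a noisy planted spike within 3 se", {
  set.seed(31)
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  template <- function(t) t * exp(1 - t)
  ok <- replicate(200, {
    y <- template(tt) + rnorm(15, sd = 0.1)
    h <- select_bandwidth_loocv(tt, y, c(3.2, 4.4, 5.6, 6.8, 8))
    fit <- fit_local_quadratic(tt, y, h, eval_times = c(0, 1, 2, 4, 8))
    all(abs(fit$fitted - template(fit$eval_times)) <=
          3 * pmax(fit$se_fitted, 1e-8) + 0.15)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_local_quadratic(c(0, 0, 1, 1), rnorm(4), 2),
               "distinct design times")
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  fit <- fit_local_quadratic(tt, rnorm(15), 8)
  expect_error(simultaneous_band(fit, 1.5), "alpha")
})
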