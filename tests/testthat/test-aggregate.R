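make_fake_series <- function(times, log_est, Sigma) {
  structure(list(times = times, est = exp(log_est), log_est = log_est,
                 Sigma = Sigma, Sigma_raw = Sigma * NA,
                 n_by_year = rep(1L, length(times))),
            class = "svyjp_series")
}

test_that("GLS with identity covariance equals OLS", {
  set.seed(31)
  times <- 2000:2014
  g <- 0.3 + 0.02 * (times - 2000) + rnorm(15, sd = 0.05)
  s <- make_fake_series(times, g, diag(15))
  f <- fit_aggregate(s, taus = numeric(), use_cov = TRUE)
  ols <- unname(coef(lm(g ~ times)))
  expect_equal(unname(f$theta), ols, tolerance = 1e-10)
  expect_equal(f$wsse, sum(resid(lm(g ~ times))^2), tolerance = 1e-10)
})

test_that("self-weighting one-PSU-per-record data gives per-year means and a diagonal covariance", {
  set.seed(32)
  times <- rep(2000:2005, each = 40)
  y <- exp(rnorm(length(times), mean = 1, sd = 0.3))
  d <- svytrend_data(rep(1, length(times)), seq_along(times),
                     rep(1, length(times)), times, y, "lognormal")
  s <- yearly_series(d)
  expect_equal(s$est, as.vector(tapply(y, times, mean)), tolerance = 1e-12,
               ignore_attr = TRUE)
  off <- s$Sigma[upper.tri(s$Sigma)]
  expect_equal(max(abs(off)), 0)
  # diagonal close to the delta-method variance of the log mean
  v1 <- var(y[times == 2000]) / 40 / mean(y[times == 2000])^2
  expect_equal(s$Sigma[1, 1], v1, tolerance = 0.05)
})

test_that("years sharing no PSUs have exactly zero estimated covariance", {
  set.seed(33)
  n <- 240
  times <- rep(2000:2003, each = 60)
  psu <- c(rep(1:6, each = 10), rep(1:6, each = 10),      # 2000-2001 shared
           rep(7:12, each = 10), rep(7:12, each = 10))    # 2002-2003 shared
  u <- rnorm(12, 0, 0.3)
  y <- exp(1 + u[psu] + rnorm(n, 0, 0.4))
  d <- svytrend_data(rep(1, n), psu, rep(1, n), times, y, "lognormal")
  s <- yearly_series(d)
  expect_equal(s$Sigma[1, 3], 0)
  expect_equal(s$Sigma[2, 4], 0)
  expect_gt(abs(s$Sigma[1, 2]), 0)      # shared PSUs give nonzero covariance
})

test_that("aggregate GLS recovers parameters as noise vanishes", {
  times <- 2000:2015
  theta_true <- c(0.4, 0.05, -0.08)
  g <- drop(jp_basis(times, 2008) %*% theta_true)
  s <- make_fake_series(times, g + rnorm(16, sd = 1e-8), diag(16) * 1e-6)
  f <- fit_aggregate(s, taus = 2008, use_cov = TRUE)
  expect_equal(unname(f$theta), theta_true, tolerance = 1e-5)
})

test_that("WBIC follows the printed formula and selects by its minimum", {
  set.seed(34)
  times <- 2000:2019
  g <- 0.5 + 0.02 * (times - 2000) - 0.06 * pmax(times - 2009, 0) +
    rnorm(20, sd = 0.01)
  s <- make_fake_series(times, g, diag(20) * 0.01^2)
  w <- wbic_select(s, k_max = 2, use_cov = TRUE)
  expect_equal(w$chosen_k, 1L)
  expect_equal(w$chosen_taus, 2009)
  # formula check against a direct computation for k = 0
  f0 <- fit_aggregate(s, numeric(), use_cov = TRUE)
  expect_equal(w$table$wbic[w$table$k == 0],
               log(f0$wsse / 20) + 2 * log(20) / 20, tolerance = 1e-12)
  # and the penalty increment between k and k+1 is 2 ln(T)/T
  pen <- w$table$wbic - log(w$table$wsse / 20)
  expect_equal(diff(pen), rep(2 * log(20) / 20, 2), tolerance = 1e-12)
})

test_that("degenerate series are rejected with clear errors", {
  # a year with a single PSU
  times <- c(2000, 2000, 2001)
  d <- svytrend_data(rep(1, 3), c(1, 2, 1), rep(1, 3), times, c(1, 2, 3),
                     "lognormal")
  expect_error(yearly_series(d), ">= 2 PSUs")
  # full covariance singular when PSUs are too few for T
  set.seed(35)
  times <- rep(2000:2009, each = 4)
  psu <- rep(1:4, times = 10)
  y <- exp(rnorm(40, 1, 0.2))
  d2 <- svytrend_data(rep(1, 40), psu, rep(1, 40), times, y, "lognormal")
  s2 <- yearly_series(d2)
  expect_error(fit_aggregate(s2, use_cov = TRUE), "singular")
})

test_that("write_series emits estimate and covariance files that read back", {
  set.seed(36)
  times <- rep(2000:2004, each = 30)
  psu <- rep(rep(1:6, each = 5), times = 5)
  y <- exp(rnorm(150, 1, 0.2))
  d <- svytrend_data(rep(1, 150), psu, rep(1, 150), times, y, "lognormal")
  s <- yearly_series(d)
  stem <- tempfile()
  write_series(s, stem)
  est <- read.csv(paste0(stem, "_est.csv"))
  cov <- as.matrix(read.csv(paste0(stem, "_cov.csv")))
  expect_equal(est$estimate, s$est, tolerance = 1e-6)
  expect_equal(unname(cov), unname(s$Sigma), tolerance = 1e-6)
  expect_equal(cov, t(cov), tolerance = 1e-12, ignore_attr = TRUE)
})
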