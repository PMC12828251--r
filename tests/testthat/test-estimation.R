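test_that("lognormal fit equals the record-level WLS oracle to 1e-10", {
  df <- make_instance12("lognormal")
  d <- svytrend_data(df$stratum, df$psu, df$weight, df$time, df$y,
                     "lognormal")
  fit <- fit_joinpoint(d, taus = numeric())
  X <- jp_basis(df$time)
  th <- oracle_wls(X, df$weight, log(df$y))
  expect_equal(unname(fit$theta), unname(th), tolerance = 1e-10)
  sse <- sum(df$weight * (log(df$y) - drop(X %*% th))^2)
  expect_equal(fit$sse, sse, tolerance = 1e-10)
  expect_equal(fit$mse, sse / sum(df$weight), tolerance = 1e-10)
})

test_that("sandwich covariance equals the brute-force oracle to 1e-10", {
  df <- make_instance12("lognormal")
  d <- svytrend_data(df$stratum, df$psu, df$weight, df$time, df$y,
                     "lognormal")
  fit <- fit_joinpoint(d, taus = numeric())
  X <- jp_basis(df$time)
  r <- log(df$y) - drop(X %*% fit$theta)
  V <- oracle_sandwich(X, df$weight, r, df$stratum, df$psu, fit$bread)
  expect_lt(max(abs(fit$V - V)) / max(abs(V)), 1e-10)
})

test_that("model covariance J reduces to the printed form for unit weights", {
  d <- make_iid_dataset(n_per_time = 10, times = 2000:2005, seed = 3)
  fit <- fit_joinpoint(d, taus = numeric())
  X <- jp_basis(d$records$time)
  n <- nrow(X); p <- ncol(X)
  sigma2 <- fit$sse / (n - p)             # classical, since all weights = 1
  expect_equal(fit$J, sigma2 * solve(crossprod(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("logistic fit matches an independent optimizer to 1e-8", {
  set.seed(11)
  n <- 400
  t <- rep(0:7, each = 50)
  cl <- rep(rep(1:10, each = 5), times = 8)
  w <- runif(n, 0.5, 2)
  y <- rbinom(n, 1, plogis(-1 + 0.1 * t))
  d <- svytrend_data(rep(1, n), cl, w, t, y, "logistic")
  fit <- fit_joinpoint(d, taus = numeric())
  X <- jp_basis(t)
  th <- oracle_logistic(X, w, y, start = c(qlogis(weighted.mean(y, w)), 0))
  expect_equal(unname(fit$theta), unname(th), tolerance = 1e-5)
  # and against stats::glm's independent IRLS, to tighter tolerance
  th_glm <- unname(coef(glm(y ~ t, family = quasibinomial, weights = w)))
  expect_equal(unname(fit$theta), th_glm, tolerance = 1e-8)

  # sandwich against the oracle on the score residual y - pi
  r <- y - plogis(drop(X %*% fit$theta))
  V <- oracle_sandwich(X, w, r, rep(1, n), cl, fit$bread)
  expect_lt(max(abs(fit$V - V)) / max(abs(V)), 1e-10)
})

test_that("estimates and both covariances are invariant to the weight scale", {
  df <- make_instance12("lognormal")
  d1 <- svytrend_data(df$stratum, df$psu, df$weight, df$time, df$y,
                      "lognormal")
  d2 <- svytrend_data(df$stratum, df$psu, df$weight * 250, df$time, df$y,
                      "lognormal")
  f1 <- fit_joinpoint(d1, numeric())
  f2 <- fit_joinpoint(d2, numeric())
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
  expect_equal(f1$V, f2$V, tolerance = 1e-6)
  expect_equal(f1$J, f2$J, tolerance = 1e-6)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("general parameterization equals independent per-segment fits", {
  d <- make_iid_dataset(n_per_time = 20, times = 2000:2011,
                        taus = 2005, slopes = c(0.05, -0.03), seed = 7)
  fit <- fit_joinpoint(d, taus = 2005, parameterization = "general")
  rec <- d$records
  keep <- rec$time != 2005                 # offending observations deleted
  expect_equal(fit$n_used, sum(keep))
  seg1 <- rec$time < 2005
  th1 <- oracle_wls(cbind(1, rec$time[seg1]), rec$weight[seg1],
                    log(rec$y[seg1]))
  seg2 <- rec$time > 2005
  th2 <- oracle_wls(cbind(1, rec$time[seg2]), rec$weight[seg2],
                    log(rec$y[seg2]))
  expect_equal(unname(fit$theta), c(th1, th2), tolerance = 1e-9)
})

test_that("cell-level fitting is exact: record order never matters", {
  df <- make_instance12("lognormal")
  set.seed(42)
  perm <- sample(nrow(df))
  d1 <- svytrend_data(df$stratum, df$psu, df$weight, df$time, df$y,
                      "lognormal")
  d2 <- svytrend_data(df$stratum[perm], df$psu[perm], df$weight[perm],
                      df$time[perm], df$y[perm], "lognormal")
  f1 <- fit_joinpoint(d1, numeric())
  f2 <- fit_joinpoint(d2, numeric())
  expect_equal(f1$theta, f2$theta)
  expect_equal(f1$V, f2$V)
})

test_that("singleton stratum triggers a variance-estimation error", {
  df <- make_instance12("lognormal")
  df$stratum[df$stratum == 2 & df$psu != 1] <- 3   # stratum 2 left with 1 PSU
  d <- svytrend_data(df$stratum, df$psu, df$weight, df$time, df$y,
                     "lognormal")
  expect_error(fit_joinpoint(d, numeric()), "singleton stratum")
})
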