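test_that("default k_max follows the series-length rule", {
  expect_equal(default_k_max(6), 0L)
  expect_equal(default_k_max(7), 1L)
  expect_equal(default_k_max(12), 2L)
  expect_equal(default_k_max(17), 3L)
  expect_equal(default_k_max(22), 4L)
  expect_equal(default_k_max(27), 5L)
  expect_equal(default_k_max(40), 5L)
})

test_that("grid candidates obey placement rules and lexicographic order", {
  expect_equal(grid_candidates(2000:2004, 2), list())     # T=5 infeasible
  expect_equal(grid_candidates(2000:2019, 0), list(numeric(0)))

  c1 <- grid_candidates(2000:2019, 1)
  expect_length(c1, 16)                                   # positions 3..18
  expect_equal(c1[[1]], 2002)
  expect_equal(c1[[16]], 2017)

  c2 <- grid_candidates(2000:2019, 2)
  expect_length(c2, 91)
  expect_equal(c2[[1]], c(2002, 2005))                    # lexicographic first
  for (cc in c2) {
    expect_gte(sum(2000:2019 < cc[1]), 2)                 # min_end before
    expect_gte(sum(2000:2019 > cc[2]), 2)                 # min_end after
    expect_gte(sum(2000:2019 > cc[1] & 2000:2019 < cc[2]), 2)  # min_between
  }
  # lexicographic ordering overall
  keys <- vapply(c2, function(x) x[1] * 1e4 + x[2], numeric(1))
  expect_false(is.unsorted(keys))
})

test_that("grid-search best model matches an independent exhaustive search", {
  # random dataset, T = 12, k in {1, 2}: oracle-equivalence property
  d <- make_iid_dataset(n_per_time = 9, times = 2005:2016,
                        taus = 2010, slopes = c(0.06, -0.04),
                        sigma = 0.25, seed = 104)
  rec <- d$records
  for (k in 1:2) {
    bm <- best_model_for_k(d, k)
    or <- oracle_grid_search(rec$time, rec$y, rec$weight, k)
    expect_equal(bm$taus, or$taus)
    expect_equal(bm$fit$sse, or$sse, tolerance = 1e-8)
  }
})

test_that("noise-free single-joinpoint data yields k = 1 at the exact tau", {
  t <- rep(2000:2015, each = 5)
  y <- exp(0.03 * (t - 2000) - 0.07 * pmax(t - 2008, 0))
  d <- svytrend_data(rep(1, length(t)), rep(1:16, times = 5), rep(1, length(t)),
                     t, y, "lognormal")
  sel <- select_joinpoints(d, k_max = 2, approach = "constrained")
  expect_equal(sel$chosen_k, 1L)
  expect_equal(sel$chosen_taus, 2008)
})

test_that("m.dAIC has the deviance form with the 2(2k+1) delta-bar penalty", {
  fake <- structure(list(link = "lognormal", k = 0, n_used = 100, mse = 0.5,
                         sum_w_used = 100), class = "svyjp_fit")
  expect_equal(m_daic(fake, delta_bar = 1), 100 * log(0.5) + 2)
  fake$k <- 2
  expect_equal(m_daic(fake, delta_bar = 3), 100 * log(0.5) + 2 * 5 * 3)

  # logistic, self-weighting: n/N = 1 so the fit term is -2logL itself
  fkl <- structure(list(link = "logistic", k = 1, n_used = 50,
                        sum_w_used = 50, neg2logl = 123), class = "svyjp_fit")
  expect_equal(m_daic(fkl, delta_bar = 2), 123 + 2 * 3 * 2)

  # penalty monotonicity in delta_bar and in k, holding the fit fixed
  expect_gt(m_daic(fkl, 3), m_daic(fkl, 2))
  fkl2 <- fkl; fkl2$k <- 2
  expect_gt(m_daic(fkl2, 2), m_daic(fkl, 2))
})

test_that("logistic m.dAIC is invariant to rescaling all weights", {
  set.seed(5)
  n <- 300
  t <- rep(2000:2009, each = 30)
  cl <- rep(rep(1:6, each = 5), times = 10)
  y <- rbinom(n, 1, 0.3)
  d1 <- svytrend_data(rep(1, n), cl, rep(2, n), t, y, "logistic")
  d2 <- svytrend_data(rep(1, n), cl, rep(500, n), t, y, "logistic")
  f1 <- fit_joinpoint(d1, numeric())
  f2 <- fit_joinpoint(d2, numeric())
  db1 <- design_effect_constrained(d1, numeric(), fit = f1)
  db2 <- design_effect_constrained(d2, numeric(), fit = f2)
  expect_equal(db1, db2, tolerance = 1e-6)
  expect_equal(m_daic(f1, db1), m_daic(f2, db2), tolerance = 1e-6)
})

test_that("design-effect traces satisfy the exact trace identities", {
  d <- make_iid_dataset(n_per_time = 15, times = 2000:2011,
                        taus = 2005, slopes = c(0.05, -0.05), seed = 9)
  # constrained: V = J => delta_bar = k + 2
  fit <- fit_joinpoint(d, 2005, "standard")
  fake <- fit; fake$V <- fit$J
  expect_equal(design_effect_constrained(d, 2005, fit = fake), 3,
               tolerance = 1e-9)
  # unconstrained: V = c J => delta_bar = c (k + 1) after intercept removal
  gen <- fit_joinpoint(d, 2005, "general")
  fakeg <- gen; fakeg$V <- 2.5 * gen$J
  expect_equal(design_effect_unconstrained(d, 2005, fit = fakeg), 2.5 * 2,
               tolerance = 1e-9)
})

test_that("clustered data inflates the constrained design effect", {
  # paired simulation: same seeds, ICC 0.3 vs 0
  db_icc <- matrix(NA_real_, 40, 2)
  for (b in 1:40) {
    set.seed(3000 + b)
    n_cl <- 30; m <- 12; T <- 8
    t <- rep(seq_len(T) + 2000, each = n_cl * m)
    cl <- rep(rep(seq_len(n_cl), each = m), times = T)
    e <- rnorm(n_cl * m * T, sd = 0.2)
    u <- rnorm(n_cl, sd = 0.2 * sqrt(0.3 / 0.7))
    for (j in 1:2) {
      z <- 0.02 * (t - 2001) + e + if (j == 1) u[cl] else 0
      d <- svytrend_data(rep(1, length(t)), cl, rep(1, length(t)), t,
                         exp(z), "lognormal")
      db_icc[b, j] <- design_effect_constrained(d, numeric())
    }
  }
  expect_gt(mean(db_icc[, 1]), mean(db_icc[, 2]))
})

test_that("selection output is identical across record orderings", {
  d <- make_iid_dataset(n_per_time = 10, times = 2000:2013,
                        taus = 2006, slopes = c(0.05, -0.04), seed = 12)
  rec <- d$records
  set.seed(99)
  perm <- sample(nrow(rec))
  d2 <- svytrend_data(rec$stratum[perm], rec$psu[perm], rec$weight[perm],
                      rec$time[perm], rec$y[perm], "lognormal")
  s1 <- select_joinpoints(d, k_max = 2)
  s2 <- select_joinpoints(d2, k_max = 2)
  expect_equal(s1$chosen_k, s2$chosen_k)
  expect_equal(s1$chosen_taus, s2$chosen_taus)
  expect_equal(s1$table$m_daic, s2$table$m_daic)
})
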