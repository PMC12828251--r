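# Independent oracle implementations used by the tests.  These are written
# from the definitions, on record-level data, without reusing any package
# internals, so agreement with the package is evidence of correctness.

# Record-level weighted least squares: theta = (X'WX)^-1 X'Wz
oracle_wls <- function(X, w, z) {
  XtWX <- t(X) %*% (X * w)
  drop(solve(XtWX, t(X) %*% (w * z)))
}

# Stratified between-PSU sandwich covariance for a linear estimating
# equation with scores u_l = w_l * x_l * r_l (r = link-scale residual):
# G = sum_i m_i/(m_i-1) sum_j (z_ij - zbar_i)(z_ij - zbar_i)',
# V = bread %*% G %*% bread.
oracle_sandwich <- function(X, w, r, stratum, psu, bread) {
  U <- X * (w * r)
  G <- matrix(0, ncol(X), ncol(X))
  for (i in unique(stratum)) {
    in_i <- stratum == i
    psus <- unique(psu[in_i])
    m <- length(psus)
    z <- t(vapply(psus, function(j) {
      colSums(U[in_i & psu == j, , drop = FALSE])
    }, numeric(ncol(X))))
    zbar <- colMeans(z)
    for (j in seq_len(m)) {
      d <- z[j, ] - zbar
      G <- G + (m / (m - 1)) * outer(d, d)
    }
  }
  bread %*% G %*% bread
}

# Weighted Bernoulli log-likelihood maximized by a generic optimizer.
oracle_logistic <- function(X, w, y, start) {
  nll <- function(theta) {
    eta <- drop(X %*% theta)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  stats::optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Exhaustive joinpoint grid search written independently: enumerate every
# k-tuple of interior observed times obeying the placement rules with
# nested loops, fit weighted LS on the hinge basis, return the tuple with
# the smallest weighted SSE.
oracle_grid_search <- function(time, y, w, k, min_end = 2, min_between = 2) {
  times <- sort(unique(time))
  T <- length(times)
  z <- log(y)
  sse_at <- function(taus) {
    X <- cbind(1, time)
    for (tau in taus) X <- cbind(X, pmax(time - tau, 0) * (time > tau))
    th <- oracle_wls(X, w, z)
    sum(w * (z - drop(X %*% th))^2)
  }
  best <- NULL; best_sse <- Inf
  pos <- seq.int(min_end + 1L, T - min_end)
  if (k == 1) {
    for (p1 in pos) {
      s <- sse_at(times[p1])
      if (s < best_sse) { best_sse <- s; best <- times[p1] }
    }
  } else if (k == 2) {
    for (p1 in pos) for (p2 in pos) {
      if (p2 - p1 >= min_between + 1L) {
        s <- sse_at(times[c(p1, p2)])
        if (s < best_sse) { best_sse <- s; best <- times[c(p1, p2)] }
      }
    }
  } else stop("oracle supports k in {1, 2}")
  list(taus = best, sse = best_sse)
}

# Central-difference numerical Jacobian.
oracle_num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps
    xm[j] <- xm[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

# A small fixed 12-record two-stratum design used in several tests.
make_instance12 <- function(link = c("lognormal", "logistic")) {
  link <- match.arg(link)
  set.seed(987)
  df <- data.frame(
    stratum = rep(c(1, 2), each = 6),
    psu = c(1, 1, 1, 2, 2, 2, 1, 1, 2, 2, 3, 3),
    weight = c(1.5, 2, 1, 3, 2.5, 1.2, 2, 1.8, 0.9, 1.1, 2.2, 1.4),
    time = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1, 2))
  df$y <- if (link == "lognormal") {
    exp(0.05 * df$time + rnorm(12, sd = 0.3)) * 20
  } else {
    rbinom(12, 1, 0.5)
  }
  df
}

# iid equal-weight dataset with every record its own PSU in one stratum.
make_iid_dataset <- function(n_per_time = 30, times = 2000:2014,
                             taus = numeric(), slopes = c(0.02),
                             sigma = 0.1, seed = 1) {
  set.seed(seed)
  t <- rep(times, each = n_per_time)
  mu <- 0.5 + slopes[1] * (t - times[1])
  for (j in seq_along(taus)) {
    mu <- mu + (slopes[j + 1] - slopes[j]) * pmax(t - taus[j], 0)
  }
  y <- exp(mu + rnorm(length(t), sd = sigma))
  svytrend_data(stratum = rep(1, length(t)), psu = seq_along(t),
                weight = rep(1, length(t)), time = t, y = y,
                link = "lognormal")
}
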