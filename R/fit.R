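#' Fit a survey-weighted joinpoint model at given joinpoint locations
#'
#' Fits the log-normal (weighted least squares on log outcome) or logistic
#' (weighted pseudo-likelihood, IRLS) joinpoint model at fixed joinpoints,
#' in either the standard continuity-constrained parameterization or the
#' general per-segment (unconstrained) parameterization.  Returns the
#' coefficient vector together with the model-based covariance `J` and the
#' design-based Taylor-linearization sandwich covariance `V` built from
#' stratum-centered PSU score totals.
#'
#' All covariates are functions of time only, so the fit is computed from
#' (stratum, PSU, time)-cell sufficient statistics; results are identical
#' to a record-level fit.
#'
#' @param data a [svytrend_data()] object.
#' @param taus sorted numeric vector of joinpoints, each an observed time
#'   point strictly inside the observed range; `numeric()` for no joinpoint.
#' @param parameterization `"standard"` (continuous at the joinpoints) or
#'   `"general"` (free per-segment lines; records at a joinpoint time are
#'   dropped).
#' @param compute_cov if `FALSE`, skip `J`/`V` (used inside the grid search
#'   where only the fit statistic is needed).
#' @return An object of class `svyjp_fit` with elements `theta`, `J`, `V`,
#'   and fit statistics `r2`/`mse` (lognormal) or `neg2logl` (logistic),
#'   plus `n_used` and `sum_w_used`.
#' @export
fit_joinpoint <- function(data, taus = numeric(),
                          parameterization = c("standard", "general"),
                          compute_cov = TRUE) {
  stopifnot(inherits(data, "svytrend"))
  parameterization <- match.arg(parameterization)
  taus <- as.numeric(taus)
  k <- length(taus)
  if (k > 0) {
    if (any(diff(taus) <= 0)) stop("taus must be strictly increasing")
    if (min(taus) <= min(data$times) || max(taus) >= max(data$times))
      stop("joinpoints must be strictly inside the observed time range")
  }

  cells <- data$cells
  if (parameterization == "general") {
    times_used <- data$times
    for (tau in taus) times_used <- times_used[!.time_eq(times_used, tau)]
    gb <- jp_general_basis(times_used, taus)
    B <- gb$X
    drop_cell <- rep(FALSE, nrow(cells))
    for (tau in taus) drop_cell <- drop_cell | .time_eq(cells$time, tau)
    cells <- cells[!drop_cell, , drop = FALSE]
    ridx <- match(cells$time, times_used)
  } else {
    times_used <- data$times
    B <- jp_basis(times_used, taus)
    ridx <- cells$tidx
  }
  p <- ncol(B)

  # per-time totals (rowsum sorts groups; re-expand onto the full time index)
  nt <- length(times_used)
  tgrp <- sort(unique(ridx))
  full <- function(v) { out <- numeric(nt); out[tgrp] <- v; out }
  s_t <- full(as.vector(rowsum(cells$sw, ridx)))
  s2_t <- full(as.vector(rowsum(cells$sw2, ridx)))
  n_used <- sum(cells$n)
  W <- sum(s_t)

  fit <- if (data$link == "lognormal") {
    .fit_lognormal_cells(cells, B, ridx, s_t, s2_t, full, n_used, W, p)
  } else {
    .fit_logistic_cells(cells, B, ridx, s_t, s2_t, full, n_used, W, p)
  }

  out <- c(fit, list(
    taus = taus, k = k, parameterization = parameterization,
    link = data$link, p = p, n_used = n_used, sum_w_used = W,
    times_used = times_used, design_df = data$design_df,
    basis = B
  ))

  if (compute_cov) {
    sc <- .psu_scores(cells, B, ridx, out)
    G <- .stratum_G(sc$z, sc$psu_stratum_used)
    out$V <- out$bread %*% G %*% out$bread
    out$V <- (out$V + t(out$V)) / 2
  }
  class(out) <- "svyjp_fit"
  out
}

.fit_lognormal_cells <- function(cells, B, ridx, s_t, s2_t, full, n_used, W, p) {
  sz_t <- full(as.vector(rowsum(cells$swz, ridx)))
  sz2 <- sum(cells$swz2)
  XtWX <- crossprod(B, B * s_t)
  Xtz <- as.vector(crossprod(B, sz_t))
  XtWXinv <- tryCatch(chol2inv(chol(XtWX)),
                      error = function(e) stop("singular fit: design matrix rank deficient"))
  theta <- as.vector(XtWXinv %*% Xtz)
  names(theta) <- colnames(B)
  sse <- sz2 - 2 * sum(theta * Xtz) + sum(theta * (XtWX %*% theta))
  sse <- max(sse, 0)
  mse <- sse / W
  sigma2 <- sse / (W * (n_used - p) / n_used)
  # model-based covariance of the *weighted* estimator under the working
  # model: sigma^2 (X'WX)^-1 (X'W^2X) (X'WX)^-1; reduces to
  # sigma^2 (X'X)^-1 for unit weights and is invariant to the weight scale
  XtW2X <- crossprod(B, B * s2_t)
  J <- sigma2 * XtWXinv %*% XtW2X %*% XtWXinv
  J <- (J + t(J)) / 2
  # weighted total SS around stratum-by-time weighted means of log y
  g <- interaction(cells$stratum, ridx, drop = TRUE)
  gsw <- as.vector(rowsum(cells$sw, g))
  gswz <- as.vector(rowsum(cells$swz, g))
  gswz2 <- as.vector(rowsum(cells$swz2, g))
  ss_tot <- sum(gswz2 - gswz^2 / gsw)
  r2 <- if (ss_tot > 0) 1 - sse / ss_tot else NA_real_
  list(theta = theta, J = J, bread = XtWXinv, mse = mse, r2 = r2,
       sse = sse, sigma2 = sigma2, neg2logl = NULL,
       fitted_by_time = as.vector(B %*% theta))
}

.fit_logistic_cells <- function(cells, B, ridx, s_t, s2_t, full, n_used, W, p) {
  sy_t <- full(as.vector(rowsum(cells$swy, ridx)))
  pbar <- sum(sy_t) / W
  pbar <- min(max(pbar, 1e-8), 1 - 1e-8)
  theta <- c(stats::qlogis(pbar), rep(0, p - 1))
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- as.vector(B %*% theta)
    pi_t <- stats::plogis(eta)
    wts <- s_t * pi_t * (1 - pi_t)
    info <- crossprod(B, B * wts)
    grad <- as.vector(crossprod(B, sy_t - pi_t * s_t))
    step <- tryCatch(solve(info, grad),
                     error = function(e) stop("singular fit: logistic information matrix"))
    theta_new <- theta + step
    rel <- max(abs(step) / (abs(theta_new) + 1e-8))
    theta <- theta_new
    if (rel < 1e-10) { converged <- TRUE; break }
  }
  if (!converged) stop("logistic fit did not converge in 100 iterations")
  eta <- as.vector(B %*% theta)
  if (any(abs(eta) > 30))
    warning("possible complete separation: |linear predictor| > 30")
  pi_t <- stats::plogis(eta)
  info <- crossprod(B, B * (s_t * pi_t * (1 - pi_t)))
  Jinv_core <- tryCatch(chol2inv(chol(info)),
                        error = function(e) stop("singular fit: logistic information matrix"))
  # model-based covariance of the weighted pseudo-ML estimator:
  # (X'WDX)^-1 (X'W^2DX) (X'WDX)^-1, weight-scale invariant
  info2 <- crossprod(B, B * (s2_t * pi_t * (1 - pi_t)))
  J <- Jinv_core %*% info2 %*% Jinv_core
  J <- (J + t(J)) / 2
  pi_c <- pmin(pmax(pi_t, 1e-12), 1 - 1e-12)
  neg2logl <- -2 * sum(sy_t * log(pi_c) + (s_t - sy_t) * log(1 - pi_c))
  names(theta) <- colnames(B)
  list(theta = theta, J = J, bread = Jinv_core, mse = NULL, r2 = NULL,
       sse = NULL, sigma2 = NULL, neg2logl = neg2logl,
       fitted_by_time = eta, pi_by_time = pi_t)
}

# PSU totals of the estimating-equation scores u = w * x * (link-scale residual)
.psu_scores <- function(cells, B, ridx, fit) {
  if (fit$link == "lognormal") {
    resid <- cells$swz - fit$fitted_by_time[ridx] * cells$sw
  } else {
    resid <- cells$swy - fit$pi_by_time[ridx] * cells$sw
  }
  U <- B[ridx, , drop = FALSE] * resid
  psu_f <- factor(cells$psu)
  z <- rowsum(U, psu_f, reorder = TRUE)
  upsu <- as.integer(levels(psu_f))
  stratum_of <- cells$stratum[match(upsu, cells$psu)]
  list(z = z, psu_stratum_used = stratum_of)
}

# between-PSU within-stratum covariance of score totals with m/(m-1) factor
.stratum_G <- function(z, stratum) {
  m <- table(stratum)
  if (any(m == 1))
    stop("singleton stratum: variance estimation needs >= 2 PSUs per stratum")
  f <- as.numeric(m[match(as.character(stratum), names(m))])
  center <- apply(z, 2, function(col) stats::ave(col, stratum))
  zc <- (z - center) * sqrt(f / (f - 1))
  crossprod(zc)
}

#' @export
print.svyjp_fit <- function(x, ...) {
  cat(sprintf("Survey-weighted %s joinpoint fit (%s parameterization)\n",
              x$link, x$parameterization))
  if (x$k > 0) cat("  joinpoints:", paste(x$taus, collapse = ", "), "\n")
  else cat("  no joinpoints\n")
  cat("  coefficients:\n")
  print(round(x$theta, 6))
  if (!is.null(x$r2)) cat(sprintf("  weighted R2 = %.6f, MSE = %.6g\n", x$r2, x$mse))
  if (!is.null(x$neg2logl)) cat(sprintf("  -2logL = %.6g\n", x$neg2logl))
  invisible(x)
}

#' @export
coef.svyjp_fit <- function(object, ...) object$theta

#' @export
vcov.svyjp_fit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$V else object$J
}
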