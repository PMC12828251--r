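#' Yearly weighted estimates with full cross-year covariance
#'
#' Computes the per-year survey-weighted ratio estimate (mean of the
#' outcome for a continuous outcome, proportion for a binary outcome),
#' log-transforms it, and estimates the full T x T covariance of the
#' log-estimates by stratified between-PSU Taylor linearization applied
#' jointly across years.  The covariance between two years accumulates
#' within-stratum cross-products of centered PSU influence totals over the
#' PSUs present in both years, so years sharing no PSUs get exactly zero
#' covariance while repeated use of the same PSUs across years yields the
#' positive covariance the aggregate model needs.
#'
#' @param data a [svytrend_data()] object.
#' @return An object of class `svyjp_series`: list with `times`, `est`
#'   (raw-scale yearly estimates), `log_est`, `Sigma` (covariance of
#'   `log_est`), `n_by_year`.
#' @export
yearly_series <- function(data) {
  stopifnot(inherits(data, "svytrend"))
  cells <- data$cells
  times <- data$times
  T <- length(times)
  W_t <- as.vector(rowsum(cells$sw, cells$tidx))
  Y_t <- as.vector(rowsum(cells$swy, cells$tidx))
  r_t <- Y_t / W_t
  if (any(r_t <= 0))
    stop("log transform undefined: a year has nonpositive weighted estimate")

  n_psu <- data$n_psu
  # PSU x year influence totals for the ratio estimator
  D <- matrix(0, n_psu, T)
  P <- matrix(FALSE, n_psu, T)
  idx <- cbind(cells$psu, cells$tidx)
  infl <- (cells$swy - r_t[cells$tidx] * cells$sw) / W_t[cells$tidx]
  # accumulate (a PSU can have several cells per year only if duplicated
  # times collapse, which svytrend_data guarantees not; still be safe)
  for (i in seq_len(nrow(cells))) {
    D[idx[i, 1], idx[i, 2]] <- D[idx[i, 1], idx[i, 2]] + infl[i]
    P[idx[i, 1], idx[i, 2]] <- TRUE
  }
  psu_per_year <- colSums(P)
  if (any(psu_per_year < 2))
    stop("variance estimation needs >= 2 PSUs in every year")

  strat <- data$psu_stratum
  Sigma <- matrix(0, T, T)
  for (i in sort(unique(strat))) {
    rows <- which(strat == i)
    Pi <- P[rows, , drop = FALSE]
    Di <- D[rows, , drop = FALSE]
    for (t1 in seq_len(T)) {
      for (t2 in t1:T) {
        shared <- Pi[, t1] & Pi[, t2]
        m <- sum(shared)
        if (m >= 2) {
          a <- Di[shared, t1]; b <- Di[shared, t2]
          v <- (m / (m - 1)) * sum((a - mean(a)) * (b - mean(b)))
          Sigma[t1, t2] <- Sigma[t1, t2] + v
          if (t2 > t1) Sigma[t2, t1] <- Sigma[t2, t1] + v
        }
      }
    }
  }
  # delta method onto the log scale
  Sigma_log <- Sigma / tcrossprod(r_t)
  n_by_year <- as.vector(rowsum(cells$n, cells$tidx))
  structure(list(times = times, est = r_t, log_est = log(r_t),
                 Sigma = Sigma_log, Sigma_raw = Sigma,
                 n_by_year = n_by_year),
            class = "svyjp_series")
}

#' @export
print.svyjp_series <- function(x, ...) {
  cat(sprintf("Yearly weighted series: %d time points\n", length(x$times)))
  print(data.frame(time = x$times, estimate = x$est,
                   se_log = sqrt(diag(x$Sigma))), row.names = FALSE)
  invisible(x)
}

#' Write a yearly series in the estimates-plus-covariance CSV layout
#'
#' Writes two files: `<stem>_est.csv` with columns time, estimate, log
#' estimate and log-scale SE, and `<stem>_cov.csv` with the full T x T
#' covariance of the log estimates, so results can be cross-checked
#' against aggregate joinpoint software.
#'
#' @param x a `svyjp_series`.
#' @param stem output path stem.
#' @export
write_series <- function(x, stem) {
  est <- data.frame(time = x$times, estimate = x$est, log_estimate = x$log_est,
                    se_log = sqrt(diag(x$Sigma)))
  utils::write.csv(est, paste0(stem, "_est.csv"), row.names = FALSE)
  cov <- as.data.frame(x$Sigma)
  names(cov) <- paste0("t", x$times)
  utils::write.csv(cov, paste0(stem, "_cov.csv"), row.names = FALSE)
  invisible(stem)
}

#' Aggregate-level GLS joinpoint fit
#'
#' Generalized least squares of the log yearly estimates on the standard
#' joinpoint basis, weighting by the inverse of the full covariance
#' (`use_cov = TRUE`) or of its diagonal only.
#'
#' @param series a [yearly_series()] object.
#' @param taus joinpoint locations (observed interior time points).
#' @param use_cov whether to use the full covariance matrix.
#' @return list with `theta`, `cov` (GLS sandwich coefficient covariance),
#'   `wsse` (weighted residual sum of squares), `taus`, `use_cov`.
#' @export
fit_aggregate <- function(series, taus = numeric(), use_cov = TRUE) {
  stopifnot(inherits(series, "svyjp_series"))
  X <- jp_basis(series$times, taus)
  g <- series$log_est
  Wm <- if (max(abs(series$Sigma)) == 0) {
    # exactly noise-free series: any GLS limit is OLS
    diag(length(g))
  } else if (use_cov) {
    tryCatch(solve(series$Sigma),
             error = function(e) stop("covariance matrix is singular"))
  } else {
    diag(1 / diag(series$Sigma))
  }
  A <- crossprod(X, Wm %*% X)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular aggregate fit"))
  theta <- as.vector(Ainv %*% crossprod(X, Wm %*% g))
  names(theta) <- colnames(X)
  resid <- g - as.vector(X %*% theta)
  wsse <- as.numeric(t(resid) %*% Wm %*% resid)
  # GLS sandwich; collapses to Ainv when Wm = Sigma^{-1}
  M <- Ainv %*% crossprod(X, Wm %*% series$Sigma %*% Wm %*% X) %*% Ainv
  list(theta = theta, cov = (M + t(M)) / 2, wsse = wsse, taus = taus,
       use_cov = use_cov)
}

#' Aggregate-level joinpoint selection by weighted BIC
#'
#' For each candidate number of joinpoints, grid-searches the joinpoint
#' locations minimizing the (co)variance-weighted residual sum of squares,
#' then selects k by the weighted BIC
#' `WBIC(k) = ln(WSSE_k / T) + (2k + 2) ln(T) / T`.
#'
#' @param series a [yearly_series()] object.
#' @param k_max maximum joinpoints (default by series length).
#' @param min_end,min_between grid placement rules.
#' @param use_cov whether the weighting uses the full covariance matrix.
#' @return list with `table` (k, taus, wsse, wbic), `chosen_k`,
#'   `chosen_taus`, `chosen_fit`.
#' @export
wbic_select <- function(series, k_max = NULL, min_end = 2, min_between = 2,
                        use_cov = TRUE) {
  stopifnot(inherits(series, "svyjp_series"))
  T <- length(series$times)
  if (is.null(k_max)) k_max <- default_k_max(T)
  rows <- list(); fits <- list()
  for (k in 0:k_max) {
    cands <- grid_candidates(series$times, k, min_end, min_between)
    if (length(cands) == 0) next
    best <- NULL; best_wsse <- Inf
    for (taus in cands) {
      f <- tryCatch(fit_aggregate(series, taus, use_cov = use_cov),
                    error = function(e) NULL)
      if (!is.null(f) && f$wsse < best_wsse) { best <- f; best_wsse <- f$wsse }
    }
    if (is.null(best)) next
    wbic <- log(best_wsse / T) + (2 * k + 2) * log(T) / T
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, taus = paste(best$taus, collapse = ","),
      wsse = best_wsse, wbic = wbic, stringsAsFactors = FALSE)
    fits[[as.character(k)]] <- best
  }
  if (length(rows) == 0) stop("no feasible aggregate model")
  tab <- do.call(rbind, rows)
  best_i <- which.min(tab$wbic)   # ties: first = smaller k
  chosen_k <- tab$k[best_i]
  list(table = tab, chosen_k = chosen_k,
       chosen_taus = fits[[as.character(chosen_k)]]$taus,
       chosen_fit = fits[[as.character(chosen_k)]],
       use_cov = use_cov)
}
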