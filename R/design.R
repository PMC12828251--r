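#' Standard (continuity-constrained) joinpoint basis
#'
#' Row basis of the standard parameterization: for joinpoints
#' `tau_1 < ... < tau_k`, each time t maps to
#' `[1, t, (t - tau_1)^+, ..., (t - tau_k)^+]` where `(t - tau)^+ =
#' (t - tau) * 1(t > tau)` with a strict inequality at the joinpoint.  The
#' implied mean function is continuous in t at every joinpoint.
#'
#' @param times numeric vector of time values.
#' @param taus sorted numeric vector of joinpoints (may be empty).
#' @return numeric matrix with `2 + length(taus)` columns.
#' @export
jp_basis <- function(times, taus = numeric()) {
  k <- length(taus)
  if (k > 1 && any(diff(taus) <= 0)) stop("taus must be strictly increasing")
  X <- cbind(1, times)
  colnames(X) <- c("(Intercept)", "time")
  for (j in seq_len(k)) {
    X <- cbind(X, ifelse(times > taus[j], times - taus[j], 0))
    colnames(X)[2 + j] <- paste0("jp", j)
  }
  X
}

# strict-equality test with a small relative tolerance for times stored
# with noise; on an observed time grid this is exact comparison
.time_eq <- function(t, tau) {
  abs(t - tau) <= 1e-9 * pmax(abs(t), abs(tau), 1)
}

#' General (unconstrained) segmented basis
#'
#' Per-segment intercept and slope columns without continuity at the
#' joinpoints.  Segment s covers `B_s = [tau_{s-1}, tau_s)` half-open, with
#' `B_1` starting at `min(times)` and the last segment closed at
#' `max(times)`.  Observations whose time equals a joinpoint ("offending
#' observations") are flagged for deletion.
#'
#' @param times numeric vector of time values.
#' @param taus sorted interior joinpoints (may be empty).
#' @return list with `X` (matrix for kept rows, `2 * (k + 1)` columns),
#'   `keep` (logical mask over `times`), and `segment` (segment index of
#'   each kept row).
#' @export
jp_general_basis <- function(times, taus = numeric()) {
  k <- length(taus)
  if (k > 1 && any(diff(taus) <= 0)) stop("taus must be strictly increasing")
  keep <- rep(TRUE, length(times))
  for (tau in taus) keep <- keep & !.time_eq(times, tau)
  t_kept <- times[keep]
  seg <- findInterval(t_kept, taus) + 1L  # t < tau1 -> 1, ..., t > tauk -> k+1
  X <- matrix(0, nrow = length(t_kept), ncol = 2L * (k + 1L))
  cn <- character(2L * (k + 1L))
  for (s in seq_len(k + 1L)) {
    in_s <- seg == s
    if (sum(!duplicated(t_kept[in_s])) < 2L)
      stop(sprintf("rank deficiency: segment %d has fewer than 2 distinct time values", s))
    X[in_s, 2L * s - 1L] <- 1
    X[in_s, 2L * s] <- t_kept[in_s]
    cn[2L * s - 1L] <- paste0("seg", s, ".int")
    cn[2L * s] <- paste0("seg", s, ".slope")
  }
  colnames(X) <- cn
  list(X = X, keep = keep, segment = seg)
}

#' Segment slopes and intercepts from the constrained coefficient vector
#'
#' For `theta = (beta0, beta1, delta_1, ..., delta_k)` the slope of segment
#' s is `beta1 + sum_{u < s} delta_u` and its intercept is
#' `beta0 - sum_{u < s} delta_u * tau_u`.
#'
#' @param theta constrained coefficient vector of length `k + 2`.
#' @param taus the joinpoints (needed for intercepts; may be omitted when
#'   only slopes are required).
#' @return list with `slopes` (length `k + 1`) and, when `taus` is supplied,
#'   `intercepts`.
#' @export
segment_coefs <- function(theta, taus = NULL) {
  k <- length(theta) - 2L
  stopifnot(k >= 0)
  slopes <- cumsum(c(theta[2], if (k > 0) theta[3:(k + 2)]))
  out <- list(slopes = unname(slopes))
  if (!is.null(taus)) {
    stopifnot(length(taus) == k)
    out$intercepts <- unname(theta[1] - cumsum(c(0, if (k > 0) theta[3:(k + 2)] * taus)))
  }
  out
}

#' Reparameterization matrix from unconstrained to constrained coefficients
#'
#' The linear map `A_k` taking the unconstrained segment coefficients
#' `(beta_{1,0}, beta_{1,1}, ..., beta_{k+1,0}, beta_{k+1,1})` to the
#' constrained vector `(beta0, beta1, delta_1, ..., delta_k)`: row 1 picks
#' the first-segment intercept, row 2 the first-segment slope, and row
#' `2 + s` is the slope difference `beta_{s+1,1} - beta_{s,1}`.  It is the
#' exact Jacobian of the reparameterization, used to carry covariance
#' matrices from the unconstrained fit to the constrained scale.
#'
#' @param k number of joinpoints (>= 0).
#' @return a `(k + 2) x (2k + 2)` matrix.
#' @export
ak_matrix <- function(k) {
  stopifnot(k >= 0)
  A <- matrix(0, nrow = k + 2L, ncol = 2L * (k + 1L))
  A[1, 1] <- 1
  A[2, 2] <- 1
  for (s in seq_len(k)) {
    A[2L + s, 2L * s] <- -1
    A[2L + s, 2L * (s + 1L)] <- 1
  }
  A
}
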