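#' Default maximum number of joinpoints for a series length
#'
#' The grid-search default used by the NCI Joinpoint software: 0 joinpoints
#' for up to 6 time points, then one more for each additional block of five
#' time points, capped at 5.
#'
#' @param n_times number of distinct observed time points.
#' @return integer maximum k.
#' @export
default_k_max <- function(n_times) {
  if (n_times <= 6) 0L
  else if (n_times <= 11) 1L
  else if (n_times <= 16) 2L
  else if (n_times <= 21) 3L
  else if (n_times <= 26) 4L
  else 5L
}

#' Candidate joinpoint locations for the grid search
#'
#' Enumerates all strictly increasing k-tuples of interior observed time
#' points satisfying the placement rules: at least `min_end` observed
#' points strictly before the first and strictly after the last joinpoint,
#' and at least `min_between` observed points strictly between consecutive
#' joinpoints.  Tuples are returned in lexicographic order.
#'
#' @param times sorted distinct observed time points.
#' @param k number of joinpoints.
#' @param min_end minimum observed points outside the extreme joinpoints.
#' @param min_between minimum observed points between adjacent joinpoints.
#' @return list of numeric vectors (each of length k); `list(numeric(0))`
#'   for `k = 0`; an empty list when no feasible tuple exists.
#' @export
grid_candidates <- function(times, k, min_end = 2, min_between = 2) {
  stopifnot(k >= 0, min_end >= 1, min_between >= 0)
  if (k == 0) return(list(numeric(0)))
  T <- length(times)
  lo <- min_end + 1L
  hi <- T - min_end
  if (hi < lo) return(list())
  # positions p1 < ... < pk with p_{j+1} - p_j >= min_between + 1
  gap <- min_between + 1L
  out <- list()
  rec <- function(prefix, start) {
    j <- length(prefix) + 1L
    # positions left must fit: p_j + (k - j) * gap <= hi
    for (p in seq.int(start, hi)) {
      if (p + (k - j) * gap > hi) break
      if (j == k) out[[length(out) + 1L]] <<- times[c(prefix, p)]
      else rec(c(prefix, p), p + gap)
    }
  }
  rec(integer(0), lo)
  out
}

#' Best joinpoint locations for a given number of joinpoints
#'
#' Fits the standard-parameterization model at every candidate tuple from
#' [grid_candidates()] and returns the candidate with the largest weighted
#' R-squared (lognormal) or the smallest weighted -2logL (logistic).  Ties
#' go to the lexicographically smallest tuple.
#'
#' @param data a [svytrend_data()] object.
#' @param k number of joinpoints.
#' @param min_end,min_between grid placement rules, see [grid_candidates()].
#' @return list with `taus` and the refitted `fit` (with covariances), or
#'   `NULL` when no candidate is feasible.
#' @export
best_model_for_k <- function(data, k, min_end = 2, min_between = 2) {
  cands <- grid_candidates(data$times, k, min_end = min_end,
                           min_between = min_between)
  if (length(cands) == 0) return(NULL)
  best <- NULL
  best_stat <- -Inf
  for (taus in cands) {
    f <- tryCatch(
      fit_joinpoint(data, taus, "standard", compute_cov = FALSE),
      error = function(e) NULL)
    if (is.null(f)) next
    # -SSE ranks identically to R2 but stays defined when the total SS is 0
    stat <- if (data$link == "lognormal") -f$sse else -f$neg2logl
    if (is.finite(stat) && stat > best_stat) {
      best_stat <- stat
      best <- taus
    }
  }
  if (is.null(best)) stop("all candidate fits failed for k = ", k)
  list(taus = best, fit = fit_joinpoint(data, best, "standard"))
}

#' Average design effect from the constrained (continuous) fit
#'
#' Fits the standard continuity-constrained model at the given joinpoints
#' and returns `trace(J^{-1} V)` over the full coefficient vector
#' `(beta0, beta1, delta_1, ..., delta_k)`.
#'
#' @param data a [svytrend_data()] object.
#' @param taus joinpoint locations.
#' @param drop_intercept if `TRUE`, delete the intercept row/column of both
#'   covariance matrices before taking the trace (mirrors the unconstrained
#'   route; default `FALSE`, the criterion as printed).
#' @param fit optionally, an already computed constrained `svyjp_fit` at
#'   `taus` (avoids refitting).
#' @return the scalar average design effect.
#' @export
design_effect_constrained <- function(data, taus, drop_intercept = FALSE,
                                      fit = NULL) {
  if (is.null(fit)) fit <- fit_joinpoint(data, taus, "standard")
  J <- fit$J; V <- fit$V
  if (drop_intercept) { J <- J[-1, -1, drop = FALSE]; V <- V[-1, -1, drop = FALSE] }
  sum(diag(solve(J, V)))
}

#' Average design effect from the unconstrained (segmented) fit
#'
#' Fits the general per-segment model at the given joinpoints, maps its
#' model-based and sandwich covariances to the constrained coefficient
#' scale with [ak_matrix()], deletes the intercept row/column, and returns
#' `trace(Jtilde^{-1} Vtilde)` over the remaining `k + 1` slope-type
#' coefficients.
#'
#' @inheritParams design_effect_constrained
#' @param fit optionally, an already computed general-parameterization
#'   `svyjp_fit` at `taus`.
#' @return the scalar average design effect.
#' @export
design_effect_unconstrained <- function(data, taus, fit = NULL) {
  if (is.null(fit)) fit <- fit_joinpoint(data, taus, "general")
  k <- length(taus)
  A <- ak_matrix(k)
  Jt <- A %*% fit$J %*% t(A)
  Vt <- A %*% fit$V %*% t(A)
  Jt <- Jt[-1, -1, drop = FALSE]
  Vt <- Vt[-1, -1, drop = FALSE]
  sum(diag(solve(Jt, Vt)))
}

#' Modified design-based AIC
#'
#' `n * log(MSE) + 2 (2k + 1) delta_bar` for the log-normal model and
#' `(n / N) * (-2 logL) + 2 (2k + 1) delta_bar` for the logistic model,
#' where `N` is the sum of sampling weights over the records used (the
#' estimated population size), `2k + 1` counts the unknown parameters
#' excluding the intercept, and `delta_bar` is the average design effect
#' `trace(J^{-1} V)`.  Both fit terms are (scaled) deviances — the Gaussian
#' profile deviance with the weighted MSE standing in for the residual
#' variance, and the weighted Bernoulli deviance rescaled by `n/N` — so the
#' criterion is invariant to the measurement units of the outcome and to
#' the scale of the sampling weights.
#'
#' @param fit a constrained `svyjp_fit`.
#' @param delta_bar average design effect (from
#'   [design_effect_constrained()] or [design_effect_unconstrained()]).
#' @return the criterion value.
#' @export
m_daic <- function(fit, delta_bar) {
  stopifnot(inherits(fit, "svyjp_fit"), is.finite(delta_bar), delta_bar > 0)
  k <- fit$k
  pen <- 2 * (2 * k + 1) * delta_bar
  if (fit$link == "lognormal") {
    fit$n_used * log(fit$mse) + pen
  } else {
    (fit$n_used / fit$sum_w_used) * fit$neg2logl + pen
  }
}

#' Select the number and location of joinpoints by m.dAIC
#'
#' For each `k = 0, ..., k_max`, runs the grid search for the best
#' standard-parameterization model, computes the average design effect at
#' its joinpoints by the requested approach, and evaluates the modified
#' design-based AIC; the model with the smallest criterion is selected
#' (ties go to the smaller k).
#'
#' @param data a [svytrend_data()] object.
#' @param k_max maximum number of joinpoints; default from
#'   [default_k_max()] applied to the number of observed time points.
#' @param min_end,min_between grid placement rules.
#' @param approach `"constrained"` (continuity-constrained standard errors;
#'   recommended) or `"unconstrained"` (per-segment-fit standard errors).
#' @param drop_intercept_constrained see [design_effect_constrained()].
#' @return An object of class `svyjp_selection`: a list with `table` (one
#'   row per k: joinpoints, fit statistic, `delta_bar`, `m_daic`),
#'   `fits` (best constrained fit per k), `chosen_k`, `chosen_taus`,
#'   `chosen_fit` and `approach`.
#' @export
select_joinpoints <- function(data, k_max = NULL, min_end = 2,
                              min_between = 2,
                              approach = c("constrained", "unconstrained"),
                              drop_intercept_constrained = FALSE) {
  stopifnot(inherits(data, "svytrend"))
  approach <- match.arg(approach)
  if (is.null(k_max)) k_max <- default_k_max(length(data$times))
  rows <- list(); fits <- list()
  for (k in 0:k_max) {
    bm <- tryCatch(best_model_for_k(data, k, min_end, min_between),
                   error = function(e) NULL)
    if (is.null(bm)) next
    perfect <- data$link == "lognormal" && bm$fit$sse <= 0
    db <- if (perfect) NA_real_ else tryCatch({
      if (approach == "constrained")
        design_effect_constrained(data, bm$taus,
                                  drop_intercept = drop_intercept_constrained,
                                  fit = bm$fit)
      else
        design_effect_unconstrained(data, bm$taus)
    }, error = function(e) NA_real_)
    # a perfect fit has fit term -Inf: it beats any penalty, and the design
    # effect is undefined (0/0) there
    crit <- if (perfect) -Inf
            else if (is.finite(db) && db > 0) m_daic(bm$fit, db)
            else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      k = k,
      taus = paste(bm$taus, collapse = ","),
      fit_stat = if (data$link == "lognormal") bm$fit$r2 else bm$fit$neg2logl,
      delta_bar = db,
      m_daic = crit,
      stringsAsFactors = FALSE)
    fits[[as.character(k)]] <- bm$fit
  }
  if (length(rows) == 0) stop("no feasible model for any k")
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$m_daic)
  if (!any(ok)) stop("m.dAIC could not be computed for any k")
  best_i <- which(ok)[which.min(tab$m_daic[ok])]   # ties: first = smaller k
  chosen_k <- tab$k[best_i]
  chosen_fit <- fits[[as.character(chosen_k)]]
  structure(list(
    table = tab,
    fits = fits,
    chosen_k = chosen_k,
    chosen_taus = chosen_fit$taus,
    chosen_fit = chosen_fit,
    approach = approach,
    link = data$link
  ), class = "svyjp_selection")
}

#' @export
print.svyjp_selection <- function(x, ...) {
  cat(sprintf("Joinpoint selection by m.dAIC (%s approach, %s link)\n",
              x$approach, x$link))
  print(x$table, row.names = FALSE)
  cat(sprintf("Chosen: k = %d%s\n", x$chosen_k,
              if (x$chosen_k > 0)
                paste0(" at ", paste(x$chosen_taus, collapse = ", "))
              else ""))
  invisible(x)
}
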