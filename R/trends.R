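#' Annual percent change from a segment slope
#'
#' `APC = 100 (exp(beta) - 1)` for a log-scale (or logit-scale, giving the
#' odds APC) segment slope, with a confidence interval obtained on the
#' slope scale using a t quantile with the design degrees of freedom (a z
#' quantile is substituted for large df).
#'
#' @param slope estimated segment slope on the link scale.
#' @param se standard error of the slope (default 0: point estimate only).
#' @param df degrees of freedom for the t quantile (design df: sampled PSUs
#'   minus strata).
#' @param conf.level confidence level, default 0.95.
#' @param z_df df threshold above which a z-interval is used (default 200).
#' @return named numeric vector `c(apc, lower, upper)`, in percent.
#' @export
apc <- function(slope, se = 0, df = Inf, conf.level = 0.95, z_df = 200) {
  stopifnot(se >= 0, df >= 1)
  q <- if (df > z_df) stats::qnorm(1 - (1 - conf.level) / 2)
       else stats::qt(1 - (1 - conf.level) / 2, df = df)
  phi <- se * q
  c(apc = 100 * (exp(slope) - 1),
    lower = 100 * (exp(slope - phi) - 1),
    upper = 100 * (exp(slope + phi) - 1))
}

#' Average annual percent change over an interval
#'
#' Length-weighted geometric average of the per-segment annual percent
#' changes: `AAPC = 100 (exp(sum(gamma_s beta_s) / sum(gamma_s)) - 1)`.
#' The confidence interval uses a z quantile on the log scale with variance
#' `gamma_tilde' V gamma_tilde`, where `V` is the covariance of the
#' segment-slope estimates from the unconstrained fit.
#'
#' @param slopes per-segment slopes on the link scale (constrained fit).
#' @param gammas segment lengths within the summary interval (same length).
#' @param V covariance matrix of the segment-slope estimates; `NULL` or 0
#'   for a point estimate with a zero-width interval.
#' @param conf.level confidence level, default 0.95.
#' @return named numeric vector `c(aapc, lower, upper)`, in percent.
#' @export
aapc <- function(slopes, gammas, V = NULL, conf.level = 0.95) {
  s <- length(slopes)
  if (length(gammas) != s) stop("slopes and gammas must have equal length")
  if (is.null(V)) V <- matrix(0, s, s)
  V <- as.matrix(V)
  if (!all(dim(V) == c(s, s))) stop("V must be ", s, " x ", s)
  gt <- gammas / sum(gammas)
  est <- sum(gt * slopes)
  se <- sqrt(max(0, as.numeric(t(gt) %*% V %*% gt)))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  c(aapc = 100 * (exp(est) - 1),
    lower = 100 * (exp(est - z * se) - 1),
    upper = 100 * (exp(est + z * se) - 1))
}

#' Trend summary: per-segment APC and overall AAPC with confidence intervals
#'
#' Point estimates come from the slopes of the continuity-constrained fit
#' at the chosen joinpoints; standard errors and the slope covariance come
#' from the unconstrained per-segment fit at the same joinpoints, which
#' accounts for joinpoint-location uncertainty.  Degrees of freedom for the
#' per-segment t intervals are the design degrees of freedom.
#'
#' @param selection a `svyjp_selection` (from [select_joinpoints()]).
#' @param data the [svytrend_data()] the selection was run on.
#' @param interval numeric `c(from, to)` summary interval for the AAPC;
#'   default the full observed time range.
#' @param conf.level confidence level, default 0.95.
#' @param z_df df threshold for switching the APC interval to z.
#' @return An object of class `svyjp_trend`: a list with `segments` (data
#'   frame: from, to, slope, se, apc, lower, upper), `aapc` (named vector),
#'   `df`, `gammas`, `link`.
#' @export
trend_summary <- function(selection, data, interval = NULL,
                          conf.level = 0.95, z_df = 200) {
  stopifnot(inherits(selection, "svyjp_selection"), inherits(data, "svytrend"))
  taus <- selection$chosen_taus
  k <- length(taus)
  if (is.null(interval)) interval <- range(data$times)
  if (interval[1] < min(data$times) || interval[2] > max(data$times) ||
      interval[1] >= interval[2])
    stop("summary interval must lie within the observed time range")

  cons <- selection$chosen_fit
  slopes <- segment_coefs(cons$theta, taus)$slopes
  unc <- fit_joinpoint(data, taus, "general")
  slope_pos <- 2L * seq_len(k + 1L)
  Vs <- unc$V[slope_pos, slope_pos, drop = FALSE]
  se <- sqrt(pmax(0, diag(Vs)))
  df <- data$design_df

  bounds <- c(min(data$times), taus, max(data$times))
  seg <- data.frame(from = bounds[-length(bounds)], to = bounds[-1])
  seg$slope <- slopes
  seg$se <- se
  ci <- t(vapply(seq_len(k + 1L), function(s)
    apc(slopes[s], se[s], df = df, conf.level = conf.level, z_df = z_df),
    numeric(3)))
  seg$apc <- ci[, 1]; seg$lower <- ci[, 2]; seg$upper <- ci[, 3]

  # overlap of each segment with the summary interval
  gammas <- pmax(0, pmin(seg$to, interval[2]) - pmax(seg$from, interval[1]))
  in_int <- gammas > 0
  aapc_est <- aapc(slopes[in_int], gammas[in_int],
                   Vs[in_int, in_int, drop = FALSE], conf.level = conf.level)

  structure(list(segments = seg, aapc = aapc_est, df = df,
                 gammas = gammas, interval = interval,
                 link = selection$link),
            class = "svyjp_trend")
}

#' @export
print.svyjp_trend <- function(x, digits = 4, ...) {
  lbl <- if (x$link == "logistic") "OAPC" else "APC"
  cat(sprintf("Per-segment %s (%%), t df = %d:\n", lbl, x$df))
  seg <- x$segments
  seg[] <- lapply(seg, function(v) if (is.numeric(v)) round(v, digits) else v)
  print(seg, row.names = FALSE)
  cat(sprintf("%s over [%s, %s]: %.4g%% (%.4g%%, %.4g%%)\n",
              if (x$link == "logistic") "OAAPC" else "AAPC",
              format(x$interval[1]), format(x$interval[2]),
              x$aapc[1], x$aapc[2], x$aapc[3]))
  invisible(x)
}

#' Export a trend summary as a data frame
#'
#' Tabular layout with one row per segment plus a final AAPC row, suitable
#' for writing to CSV.
#'
#' @param x a `svyjp_trend` object.
#' @return data frame with columns segment, from, to, estimate, lower,
#'   upper.
#' @export
as.data.frame.svyjp_trend <- function(x, ...) {
  seg <- x$segments
  out <- data.frame(
    segment = c(paste0("segment", seq_len(nrow(seg))), "AAPC"),
    from = c(seg$from, x$interval[1]),
    to = c(seg$to, x$interval[2]),
    estimate = c(seg$apc, x$aapc[1]),
    lower = c(seg$lower, x$aapc[2]),
    upper = c(seg$upper, x$aapc[3]))
  out
}
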