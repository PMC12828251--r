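#' Survey-weighted joinpoint regression
#'
#' The main model-fitting interface: selects the number and location of
#' joinpoints in the time trend of a survey outcome by grid search and the
#' modified design-based AIC, then summarizes the trend as per-segment
#' annual percent changes (APC; odds APC for the logistic link) and the
#' average APC with design-correct confidence intervals.
#'
#' @param formula model formula of the form `y ~ time`; the right-hand side
#'   must be a single time variable (individual-level covariates are not
#'   supported).
#' @param data a data frame with the outcome, time, weight and design
#'   columns, or an existing [svytrend_data()] object (in which case
#'   `formula`, `weights`, `strata` and `psu` are ignored).
#' @param weights sampling weight column: a one-sided formula (`~w`) or a
#'   character column name.
#' @param strata stratum column (formula or name).
#' @param psu primary-sampling-unit column (formula or name), scoped within
#'   stratum.
#' @param link `"lognormal"` for positive continuous outcomes or
#'   `"logistic"` for binary outcomes.
#' @param approach design-effect route for the m.dAIC: `"constrained"`
#'   (recommended) or `"unconstrained"`.
#' @param k_max maximum number of joinpoints (default by series length,
#'   see [default_k_max()]).
#' @param min_end,min_between grid placement rules, see [grid_candidates()].
#' @param interval AAPC summary interval, default the full observed range.
#' @return An object of class `svyjoinpoint` with components `selection`
#'   (the per-k m.dAIC table and fits), `trend` (APC/AAPC summary),
#'   `data` (the `svytrend` design object) and `call`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `fitted`.
#' @examples
#' set.seed(1)
#' t <- rep(2000:2015, each = 40)
#' cl <- rep(rep(1:8, each = 5), times = 16)
#' mu <- 0.02 * (t - 2000) - 0.05 * pmax(t - 2008, 0)
#' y <- exp(mu + rnorm(length(t), sd = 0.1)) * 25
#' d <- data.frame(y = y, year = t, w = 1, st = 1, cl = cl)
#' m <- svyjoinpoint(y ~ year, d, weights = ~w, strata = ~st, psu = ~cl,
#'                   link = "lognormal")
#' print(m)
#' @export
svyjoinpoint <- function(formula, data, weights, strata, psu,
                         link = c("lognormal", "logistic"),
                         approach = c("constrained", "unconstrained"),
                         k_max = NULL, min_end = 2, min_between = 2,
                         interval = NULL) {
  link <- match.arg(link)
  approach <- match.arg(approach)
  cl <- match.call()

  if (inherits(data, "svytrend")) {
    d <- data
  } else {
    vars <- all.vars(formula)
    if (length(vars) != 2)
      stop("formula must be of the form outcome ~ time")
    getcol <- function(spec, what) {
      if (missing(spec)) stop("argument '", what, "' is required")
      nm <- if (inherits(spec, "formula")) all.vars(spec) else as.character(spec)
      if (length(nm) != 1 || !nm %in% names(data))
        stop("column for '", what, "' not found in data")
      data[[nm]]
    }
    d <- svytrend_data(stratum = getcol(strata, "strata"),
                       psu = getcol(psu, "psu"),
                       weight = getcol(weights, "weights"),
                       time = data[[vars[2]]],
                       y = data[[vars[1]]],
                       link = link)
  }

  sel <- select_joinpoints(d, k_max = k_max, min_end = min_end,
                           min_between = min_between, approach = approach)
  tr <- trend_summary(sel, d, interval = interval)
  structure(list(selection = sel, trend = tr, data = d, call = cl),
            class = "svyjoinpoint")
}

#' @export
print.svyjoinpoint <- function(x, ...) {
  cat("Survey-weighted joinpoint regression\n\n")
  print(x$selection)
  cat("\n")
  print(x$trend)
  invisible(x)
}

#' @export
summary.svyjoinpoint <- function(object, ...) {
  structure(list(selection_table = object$selection$table,
                 chosen_k = object$selection$chosen_k,
                 chosen_taus = object$selection$chosen_taus,
                 coefficients = object$selection$chosen_fit$theta,
                 trend = object$trend,
                 design_df = object$data$design_df,
                 n = object$data$n,
                 approach = object$selection$approach,
                 link = object$selection$link),
            class = "summary.svyjoinpoint")
}

#' @export
print.summary.svyjoinpoint <- function(x, ...) {
  cat(sprintf("Survey joinpoint model (%s link, %s approach)\n", x$link,
              x$approach))
  cat(sprintf("n = %d records, design df = %d\n\n", x$n, x$design_df))
  cat("Model selection (m.dAIC):\n")
  print(x$selection_table, row.names = FALSE)
  cat(sprintf("\nChosen model: %d joinpoint(s)%s\n", x$chosen_k,
              if (x$chosen_k > 0)
                paste0(" at ", paste(x$chosen_taus, collapse = ", ")) else ""))
  cat("\nConstrained coefficients:\n")
  print(round(x$coefficients, 6))
  cat("\n")
  print(x$trend)
  invisible(x)
}

#' @export
coef.svyjoinpoint <- function(object, ...) object$selection$chosen_fit$theta

#' Predicted trend values
#'
#' Evaluates the chosen constrained model at new time points, on the link
#' scale (`type = "link"`) or the response scale (`type = "response"`:
#' geometric-mean outcome for the lognormal link, probability for the
#' logistic link).
#'
#' @param object a fitted `svyjoinpoint` model.
#' @param newtimes time points at which to predict; default the observed
#'   time points.
#' @param type `"link"` or `"response"`.
#' @param ... unused.
#' @export
predict.svyjoinpoint <- function(object, newtimes = NULL,
                                 type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newtimes)) newtimes <- object$data$times
  X <- jp_basis(newtimes, object$selection$chosen_taus)
  eta <- as.vector(X %*% coef(object))
  if (type == "link") eta
  else if (object$selection$link == "lognormal") exp(eta)
  else stats::plogis(eta)
}

#' @export
fitted.svyjoinpoint <- function(object, ...) {
  predict(object, newtimes = object$data$times, type = "link")
}

#' Plot the yearly weighted estimates with the fitted joinpoint trend
#'
#' Plots the per-year survey-weighted estimate (geometric mean for the
#' lognormal link, proportion for the logistic link) and overlays the
#' fitted segmented trend, marking the chosen joinpoints.
#'
#' @param x a fitted `svyjoinpoint` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.svyjoinpoint <- function(x, ...) {
  d <- x$data
  cells <- d$cells
  sw <- rowsum(cells$sw, cells$tidx)
  if (d$link == "lognormal") {
    est <- exp(as.vector(rowsum(cells$swz, cells$tidx)) / as.vector(sw))
    ylab <- "weighted geometric mean"
  } else {
    est <- as.vector(rowsum(cells$swy, cells$tidx)) / as.vector(sw)
    ylab <- "weighted proportion"
  }
  grid <- seq(min(d$times), max(d$times), length.out = 200)
  fitv <- predict(x, grid, type = "response")
  graphics::plot(d$times, est, xlab = "time", ylab = ylab,
                 ylim = range(c(est, fitv)), ...)
  graphics::lines(grid, fitv, col = "steelblue", lwd = 2)
  if (x$selection$chosen_k > 0)
    graphics::abline(v = x$selection$chosen_taus, lty = 3, col = "grey40")
  invisible(x)
}
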