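#' Individual-level survey trend data
#'
#' Container for individual records from a stratified multistage cluster
#' sample observed over time: stratum, primary sampling unit (PSU), sampling
#' weight, time value and outcome.  PSU identifiers are scoped within
#' stratum, so the same PSU code appearing in two strata counts as two PSUs
#' (the with-replacement first-stage approximation used throughout).
#'
#' Internally the constructor also collapses the records to
#' (stratum, PSU, time) cells carrying the weighted sufficient statistics
#' that every model fit in this package needs; because all model covariates
#' are functions of time only, fits on cells are exactly equal to fits on
#' records.
#'
#' @param stratum vector of stratum labels.
#' @param psu vector of PSU labels (unique within stratum).
#' @param weight positive sampling weights (inverse inclusion probabilities).
#' @param time numeric time values (calendar years expected).
#' @param y outcome: positive continuous for `link = "lognormal"`, 0/1 for
#'   `link = "logistic"`.
#' @param link outcome model family, `"lognormal"` or `"logistic"`.
#' @return An object of class `svytrend`: a list with the validated
#'   `records` data frame, the collapsed `cells`, the sorted distinct
#'   `times`, counts `n`, `n_strata`, `n_psu`, `sum_w` and the design
#'   degrees of freedom `design_df = n_psu - n_strata`.
#' @export
svytrend_data <- function(stratum, psu, weight, time, y,
                          link = c("lognormal", "logistic")) {
  link <- match.arg(link)
  n0 <- length(y)
  stopifnot(length(stratum) == n0, length(psu) == n0,
            length(weight) == n0, length(time) == n0)
  keep <- stats::complete.cases(stratum, psu, weight, time, y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d record(s) with missing fields", n_dropped))
    stratum <- stratum[keep]; psu <- psu[keep]
    weight <- weight[keep]; time <- time[keep]; y <- y[keep]
  }
  if (length(y) == 0L) stop("no complete records")
  weight <- as.numeric(weight)
  time <- as.numeric(time)
  y <- as.numeric(y)
  if (any(weight <= 0)) stop("validation error: all weights must be > 0")
  if (link == "lognormal") {
    if (any(y <= 0))
      stop("validation error: lognormal link requires outcome > 0")
  } else {
    if (!all(y %in% c(0, 1)))
      stop("validation error: logistic link requires outcome in {0, 1}")
  }

  stratum_f <- factor(stratum)
  # PSU scoped within stratum
  psu_f <- factor(paste(as.integer(stratum_f), psu, sep = "\r"))
  times <- sort(unique(time))
  if (length(times) < 2L) stop("need at least 2 distinct time points")
  n_strata <- nlevels(stratum_f)
  n_psu <- nlevels(psu_f)
  if (n_psu - n_strata < 1L)
    stop("degenerate design: need design_df = n_psu - n_strata >= 1")

  records <- data.frame(stratum = stratum, psu = psu, weight = weight,
                        time = time, y = y, stringsAsFactors = FALSE)

  si <- as.integer(stratum_f)
  pi_ <- as.integer(psu_f)
  ti <- match(time, times)
  key <- (pi_ - 1L) * length(times) + ti      # psu x time cell
  ord <- order(key)
  uk <- !duplicated(key[ord])
  grp <- cumsum(uk)
  first <- ord[uk]
  agg <- function(v) as.vector(rowsum(v[ord], grp, reorder = FALSE))
  cells <- data.frame(
    stratum = si[first],
    psu     = pi_[first],
    time    = time[first],
    tidx    = ti[first],
    n       = agg(rep(1, length(key))),
    sw      = agg(weight),
    sw2     = agg(weight * weight),
    swy     = agg(weight * y)
  )
  if (link == "lognormal") {
    z <- log(y)
    cells$swz  <- agg(weight * z)
    cells$swz2 <- agg(weight * z * z)
  }

  # stratum index for each psu index 1..n_psu
  u <- !duplicated(cells$psu)
  psu_stratum <- integer(n_psu)
  psu_stratum[cells$psu[u]] <- cells$stratum[u]

  structure(list(
    records = records,
    cells = cells,
    link = link,
    times = times,
    n = nrow(records),
    sum_w = sum(weight),
    n_strata = n_strata,
    n_psu = n_psu,
    design_df = n_psu - n_strata,
    psu_stratum = psu_stratum,
    stratum_levels = levels(stratum_f)
  ), class = "svytrend")
}

#' Read individual-level survey records from a delimited text file
#'
#' @param path path to a CSV file with a header row.
#' @param columns named character vector mapping the logical fields
#'   `stratum`, `psu`, `weight`, `time`, `y` to column names in the file.
#' @param link outcome family, see [svytrend_data()].
#' @param sep field separator, default comma.
#' @return A [svytrend_data()] object.
#' @export
read_survey_data <- function(path,
                             columns = c(stratum = "stratum", psu = "psu",
                                         weight = "weight", time = "time",
                                         y = "y"),
                             link = c("lognormal", "logistic"),
                             sep = ",") {
  link <- match.arg(link)
  need <- c("stratum", "psu", "weight", "time", "y")
  full <- c(stratum = "stratum", psu = "psu", weight = "weight",
            time = "time", y = "y")
  full[names(columns)] <- columns
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(full[need]), names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  svytrend_data(stratum = df[[full["stratum"]]], psu = df[[full["psu"]]],
                weight = df[[full["weight"]]], time = df[[full["time"]]],
                y = df[[full["y"]]], link = link)
}

#' Write survey records back to CSV
#'
#' Writes the record-level data in the same CSV dialect that
#' [read_survey_data()] accepts, so that a read/write cycle round-trips all
#' fields.
#'
#' @param x a `svytrend` object.
#' @param path output file path.
#' @export
write_survey_data <- function(x, path) {
  stopifnot(inherits(x, "svytrend"))
  utils::write.csv(x$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Design degrees of freedom
#'
#' Total number of sampled PSUs minus the total number of strata; the
#' degrees of freedom used for t-quantiles in APC confidence intervals.
#' A PSU present in any year counts once.
#'
#' @param x a `svytrend` object.
#' @return integer degrees of freedom (>= 1).
#' @export
design_df <- function(x) {
  stopifnot(inherits(x, "svytrend"))
  d <- x$n_psu - x$n_strata
  if (d < 1L) stop("degenerate design: fewer than 1 design degree of freedom")
  d
}

#' @export
print.svytrend <- function(x, ...) {
  cat(sprintf(
    "Survey trend data (%s): %d records, %d strata, %d PSUs, %d time points\n",
    x$link, x$n, x$n_strata, x$n_psu, length(x$times)))
  cat(sprintf("  time range %s-%s, sum of weights %.6g, design df %d\n",
              format(min(x$times)), format(max(x$times)), x$sum_w,
              x$design_df))
  invisible(x)
}
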