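#' Define a finite-population simulation scenario
#'
#' Describes a finite target population (FTP) of equal-sized clusters with
#' a single-joinpoint time trend and controllable intra-cluster
#' correlation, together with the repeated cross-sectional cluster
#' sampling design used to draw survey samples from it: the same cluster
#' set is reused for the first half of the years and a freshly drawn set
#' for the second half (mimicking a survey redesign), and individuals are
#' subsampled within sampled clusters at a fixed or uniformly varying
#' rate, with weights equal to inverse inclusion probabilities.
#'
#' Trend calibration: the pre-joinpoint slope on the link scale is
#' `log(1 + base_apc/100)` and the slope change is
#' `log(1 + (base_apc + apc_diff)/100) - log(1 + base_apc/100)`, so
#' `apc_diff` is the post-minus-pre difference in annual percent change
#' (odds APC for the logistic link); `apc_diff = 0` encodes a true
#' zero-joinpoint trend.
#'
#' @param link `"lognormal"` or `"logistic"`.
#' @param icc target intra-cluster correlation in `[0, 1)` (latent logistic
#'   scale for the binary outcome).
#' @param apc_diff change in APC (percentage points) at the joinpoint.
#' @param rate within-cluster sampling rate in (0, 1], or `"uniform"` for a
#'   rate redrawn uniformly in (0.05, 0.15) per cluster-year.
#' @param n_clusters number of equal-sized clusters in the FTP.
#' @param cluster_size individuals per cluster.
#' @param years vector of calendar years.
#' @param clusters_per_year clusters sampled each year.
#' @param joinpoint_year location of the single true joinpoint.
#' @param base_apc pre-joinpoint APC in percent; default 0.5 (lognormal,
#'   BMI-like drift) or 4 (logistic, obesity-odds-like drift).
#' @param sigma total SD of the log outcome (lognormal link).
#' @param base_level geometric mean of the outcome in the first year
#'   (lognormal link).
#' @param base_prev outcome prevalence in the first year (logistic link).
#' @return An object of class `jp_scenario` (a validated list).
#' @export
jp_scenario <- function(link = c("lognormal", "logistic"),
                        icc = 0, apc_diff = 0, rate = 0.05,
                        n_clusters = 1000, cluster_size = 1000,
                        years = 1997:2016, clusters_per_year = 80,
                        joinpoint_year = 2006,
                        base_apc = if (match.arg(link) == "lognormal") 0.5 else 4,
                        sigma = 0.2, base_level = 27, base_prev = 0.2) {
  link <- match.arg(link)
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)")
  uniform_rate <- identical(rate, "uniform")
  if (!uniform_rate) {
    rate <- as.numeric(rate)
    if (!is.finite(rate) || rate <= 0 || rate > 1)
      stop("rate must be in (0, 1] or \"uniform\"")
  }
  if (clusters_per_year > n_clusters)
    stop("clusters_per_year cannot exceed n_clusters")
  years <- sort(as.numeric(years))
  if (length(years) < 4) stop("need at least 4 years")
  if (joinpoint_year <= min(years) || joinpoint_year >= max(years))
    stop("joinpoint_year must be strictly inside the year range")
  half <- ceiling(length(years) / 2)
  blocks <- list(seq_len(half), seq.int(half + 1L, length(years)))
  s1 <- log(1 + base_apc / 100)
  s2 <- log(1 + (base_apc + apc_diff) / 100)
  structure(list(
    link = link, icc = icc, apc_diff = apc_diff, rate = rate,
    uniform_rate = uniform_rate,
    n_clusters = n_clusters, cluster_size = cluster_size,
    years = years, clusters_per_year = clusters_per_year,
    joinpoint_year = joinpoint_year, base_apc = base_apc,
    sigma = sigma, base_level = base_level, base_prev = base_prev,
    blocks = blocks,
    slope1 = s1, slope_change = s2 - s1,
    true_k = as.integer(apc_diff != 0)
  ), class = "jp_scenario")
}

# segmented link-scale population mean path
.mean_path <- function(sc) {
  t <- sc$years
  base <- if (sc$link == "lognormal") log(sc$base_level)
          else stats::qlogis(sc$base_prev)
  base + sc$slope1 * (t - t[1]) +
    sc$slope_change * pmax(t - sc$joinpoint_year, 0)
}

#' Generate a finite target population
#'
#' Realizes the FTP for a scenario: for the lognormal link,
#' `log y = mu(t) + u_c + e`, with cluster effects
#' `u_c ~ N(0, icc * sigma^2)` held fixed across years and individual
#' noise `e ~ N(0, (1 - icc) * sigma^2)` drawn independently per
#' individual-year; for the logistic link, a latent-scale cluster effect
#' `u_c ~ N(0, icc/(1-icc) * pi^2/3)` shifts the logit of the outcome
#' probability and individual outcomes are Bernoulli draws.
#'
#' @param scenario a [jp_scenario()].
#' @param seed integer RNG seed; the FTP is generated once per scenario and
#'   then resampled repeatedly.
#' @return An object of class `jp_population`: list with the outcome
#'   matrix `y` (individuals x years), `cluster` (cluster index per
#'   individual), the scenario, and the true mean path `mu`.
#' @export
simulate_population <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "jp_scenario"))
  set.seed(as.integer(seed))
  sc <- scenario
  n <- sc$n_clusters * sc$cluster_size
  T <- length(sc$years)
  cluster <- rep(seq_len(sc$n_clusters), each = sc$cluster_size)
  mu <- .mean_path(sc)
  if (sc$link == "lognormal") {
    sd_u <- sc$sigma * sqrt(sc$icc)
    sd_e <- sc$sigma * sqrt(1 - sc$icc)
    u <- if (sd_u > 0) stats::rnorm(sc$n_clusters, 0, sd_u) else numeric(sc$n_clusters)
    y <- matrix(stats::rnorm(n * T, 0, sd_e), n, T)
    y <- exp(sweep(y, 2, mu, "+") + u[cluster])
  } else {
    var_u <- sc$icc / (1 - sc$icc) * pi^2 / 3
    u <- if (var_u > 0) stats::rnorm(sc$n_clusters, 0, sqrt(var_u)) else numeric(sc$n_clusters)
    eta <- outer(u[cluster], mu, "+")
    y <- matrix(stats::rbinom(n * T, 1L, stats::plogis(as.vector(eta))), n, T)
  }
  structure(list(y = y, cluster = cluster, scenario = sc, mu = mu,
                 u = u, seed = as.integer(seed)),
            class = "jp_population")
}

#' Empirical intra-cluster correlation of a generated population
#'
#' One-way ANOVA estimator of the ICC of the link-scale outcome
#' (log outcome for the lognormal link, raw 0/1 for the logistic link),
#' computed per year and averaged.
#'
#' @param pop a [simulate_population()] object.
#' @return mean ICC across years.
#' @export
population_icc <- function(pop) {
  stopifnot(inherits(pop, "jp_population"))
  sc <- pop$scenario
  m <- sc$cluster_size
  K <- sc$n_clusters
  vals <- if (sc$link == "lognormal") log(pop$y) else pop$y
  iccs <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    cm <- rowsum(v, pop$cluster) / m
    ssb <- m * sum((cm - mean(v))^2)
    ssw <- sum((v - cm[pop$cluster])^2)
    msb <- ssb / (K - 1)
    msw <- ssw / (K * (m - 1))
    (msb - msw) / (msb + (m - 1) * msw)
  }, numeric(1))
  mean(iccs)
}

#' Draw one repeated cross-sectional cluster sample
#'
#' Samples `clusters_per_year` clusters by simple random sampling without
#' replacement, independently for each overlap block (the block's years
#' share the cluster set), then subsamples individuals within each sampled
#' cluster-year at the scenario's rate.  Weights are the product of the
#' inverse cluster and within-cluster inclusion probabilities.  The design
#' has a single stratum; the PSU identifier is the (block, cluster) pair,
#' so a cluster reused across a block's years is one PSU.
#'
#' @param pop a [simulate_population()] object.
#' @param seed integer seed for this replicate.
#' @return a [svytrend_data()] object.
#' @export
draw_survey_sample <- function(pop, seed = 1L) {
  stopifnot(inherits(pop, "jp_population"))
  set.seed(as.integer(seed))
  sc <- pop$scenario
  cs <- sc$cluster_size
  w_cluster <- sc$n_clusters / sc$clusters_per_year
  recs <- vector("list", length(sc$blocks) * sc$clusters_per_year *
                   max(lengths(sc$blocks)))
  ri <- 0L
  for (b in seq_along(sc$blocks)) {
    yrs <- sc$blocks[[b]]
    clusters <- sample.int(sc$n_clusters, sc$clusters_per_year)
    for (ty in yrs) {
      for (cl in clusters) {
        r <- if (sc$uniform_rate) stats::runif(1, 0.05, 0.15) else sc$rate
        m <- max(1L, round(r * cs))
        loc <- sample.int(cs, m)
        gidx <- (cl - 1L) * cs + loc
        ri <- ri + 1L
        recs[[ri]] <- list(
          psu = rep.int(b * sc$n_clusters + cl, m),
          time = rep.int(sc$years[ty], m),
          weight = rep.int(w_cluster * cs / m, m),
          y = pop$y[gidx, ty])
      }
    }
  }
  recs <- recs[seq_len(ri)]
  svytrend_data(
    stratum = rep.int(1L, sum(vapply(recs, function(r) length(r$y), 1L))),
    psu = unlist(lapply(recs, `[[`, "psu")),
    weight = unlist(lapply(recs, `[[`, "weight")),
    time = unlist(lapply(recs, `[[`, "time")),
    y = unlist(lapply(recs, `[[`, "y")),
    link = sc$link)
}
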