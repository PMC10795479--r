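#' Simulation configuration for the resampling engines
#'
#' @param reps number of replicates, >= 2; 1000 is adequate for most
#'   demographic estimators.
#' @param seed integer seed; with a fixed seed every engine is
#'   bit-reproducible because the draw order is fixed (population 1 then
#'   population 2, ages ascending, and causes ascending within age).
#' @param ci_level coverage of the percentile confidence intervals.
#' @param distribution replicate-generating assumption; the Monte Carlo
#'   engine uses `"normal-rates"`, the bootstraps use the death-count
#'   distributions.
#' @param negative_policy what to do with negative normal rate draws;
#'   the only implemented policy truncates them to zero and counts the
#'   truncations in the result.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(reps = 1000, seed = NULL, ci_level = 0.95,
                       distribution = c("normal-rates", "poisson-deaths",
                                        "binomial-deaths"),
                       negative_policy = "truncate") {
  distribution <- match.arg(distribution)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 2L) stop("'reps' must be an integer >= 2")
  if (!is.null(seed)) seed <- as.integer(seed)
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must be in (0, 1)")
  negative_policy <- match.arg(negative_policy, "truncate")
  structure(list(reps = reps, seed = seed, ci_level = ci_level,
                 distribution = distribution,
                 negative_policy = negative_policy),
            class = "sim_config")
}

#' Summarize a replicate matrix into standard errors and intervals
#'
#' The standard error of each quantity is the sample standard deviation
#' (denominator reps - 1) of its replicates; the confidence interval is
#' the percentile interval with linear interpolation between order
#' statistics (the `type = 7` quantile definition, fixed forever for
#' reproducibility). Replicates containing `NA` count as failed and are
#' excluded.
#'
#' @param replicates numeric matrix, replicates in rows, quantities in
#'   columns (a vector is treated as one column).
#' @param ci_level interval coverage in (0, 1).
#' @return list with `se`, `lower`, `upper` (per quantity), `n_ok` and
#'   `n_failed`.
#' @examples
#' summarize_replicates(cbind(c(1, 2, 3)))   # se 1, CI (1.05, 2.95)
#' @export
summarize_replicates <- function(replicates, ci_level = 0.95) {
  if (is.null(dim(replicates))) replicates <- cbind(replicates)
  ok <- stats::complete.cases(replicates)
  if (!any(ok)) stop("all replicates failed")
  if (sum(ok) < 2L) stop("fewer than 2 successful replicates")
  r <- replicates[ok, , drop = FALSE]
  alpha <- (1 - ci_level) / 2
  list(se = apply(r, 2L, stats::sd),
       lower = apply(r, 2L, stats::quantile, probs = alpha, type = 7),
       upper = apply(r, 2L, stats::quantile, probs = 1 - alpha, type = 7),
       n_ok = sum(ok), n_failed = sum(!ok))
}

# ---- internal helpers shared by the engines --------------------------------

# flatten rates and their variances for one schedule-like object, in the
# documented draw order (ages ascending; causes ascending within age)
flatten_rates <- function(x) {
  if (inherits(x, "mortality_schedule")) {
    v <- if (all(is.finite(x$rate_se))) x$rate_se^2
         else if (all(is.finite(x$exposure))) x$rate / x$exposure
         else stop("rate variances unavailable: supply exposure or rate_se")
    list(rates = x$rate, vars = v)
  } else if (inherits(x, "cause_schedule")) {
    list(rates = as.vector(t(x$rate)),
         vars = as.vector(t(x$rate / x$schedule$exposure)))
  } else stop("expected a mortality_schedule or cause_schedule")
}

# rebuild a schedule-like object with new rates (exposures fixed)
inject_rates <- function(x, r) {
  if (inherits(x, "mortality_schedule")) {
    x$rate <- r
    x
  } else {
    m <- matrix(r, nrow = nrow(x$rate), byrow = TRUE,
                dimnames = dimnames(x$rate))
    x$rate <- m
    x$schedule$rate <- rowSums(m)
    x
  }
}

# default estimators: Arriaga age contributions (+ total), or the
# age-by-cause split when given cause schedules
est_pair <- function(scheds) {
  s1 <- scheds[[1L]]; s2 <- scheds[[2L]]
  K <- nrow(s1)
  if (s1$rate[K] <= 0 || s2$rate[K] <= 0)
    stop("non-positive open-group rate: open-group expectancy undefined")
  d <- arriaga_core(lt_core(s1$rate, s1$ax, s1$n),
                    lt_core(s2$rate, s2$ax, s2$n))
  c(d, total = sum(d))
}

est_cause_pair <- function(scheds) {
  c1 <- scheds[[1L]]; c2 <- scheds[[2L]]
  s1 <- c1$schedule; s2 <- c2$schedule
  K <- nrow(s1)
  if (s1$rate[K] <= 0 || s2$rate[K] <= 0)
    stop("non-positive open-group rate: open-group expectancy undefined")
  d <- arriaga_core(lt_core(s1$rate, s1$ax, s1$n),
                    lt_core(s2$rate, s2$ax, s2$n))
  dxi <- cause_split(d, s1$rate, s2$rate, c1$rate, c2$rate)
  nm <- outer(rownames(c1$deaths), colnames(c1$deaths), paste, sep = ":")
  c(stats::setNames(as.vector(dxi), as.vector(nm)), total = sum(d))
}

default_estimator <- function(x) {
  if (length(x) == 2L && inherits(x[[1L]], "mortality_schedule") &&
      inherits(x[[2L]], "mortality_schedule")) return(est_pair)
  if (length(x) == 2L && inherits(x[[1L]], "cause_schedule") &&
      inherits(x[[2L]], "cause_schedule")) return(est_cause_pair)
  stop("no default estimator for this input; supply 'estimator'")
}

# run the replicate loop and package the result
run_replicates <- function(point, draw_one, estimator, config, method) {
  reps <- config$reps
  if (!is.null(config$seed)) set.seed(config$seed)
  Q <- length(point)
  out <- matrix(NA_real_, reps, Q, dimnames = list(NULL, names(point)))
  failures <- 0L
  truncated <- 0L
  first_err <- NULL
  for (r in seq_len(reps)) {
    drawn <- draw_one()
    truncated <- truncated + drawn$truncated
    val <- tryCatch(estimator(drawn$scheds), error = function(e) e)
    if (inherits(val, "error")) {
      failures <- failures + 1L
      if (is.null(first_err)) first_err <- conditionMessage(val)
    } else out[r, ] <- val
  }
  if (failures > 0.01 * reps)
    stop("more than 1% of replicates failed (", failures, "/", reps,
         "); first error: ", first_err)
  s <- summarize_replicates(out, config$ci_level)
  res <- list(method = method, estimate = point, se = s$se,
              lower = s$lower, upper = s$upper,
              ci_level = config$ci_level, reps = reps, seed = config$seed,
              replicates = out, failures = failures, truncated = truncated,
              labels = names(point))
  class(res) <- "decomp_uncertainty"
  res
}

#' Generic Monte Carlo standard errors for rate-based estimators
#'
#' Implements the general simulation recipe for any demographic
#' estimator that is a pure function of event rates: each replicate
#' draws every age- (and cause-) specific rate independently from a
#' normal distribution centred at the observed rate, with variance
#' `rate / exposure` (the Poisson-implied variance of a rate) or the
#' squared survey-supplied standard error when the schedule carries
#' `rate_se`. The estimator is re-evaluated on each set of drawn rates;
#' the standard deviation of the replicates is the standard error and
#' the percentile interval is the confidence interval. Exposures are
#' treated as fixed. Negative rate draws are truncated to zero and
#' counted (`truncated` in the result); with five or more deaths per
#' group truncation is vanishingly rare.
#'
#' Draws are made in a fixed order — population 1 then population 2,
#' ages ascending, causes ascending within age — so results are
#' bit-reproducible for a given seed.
#'
#' @param x a [mortality_schedule()], a [cause_schedule()], or a list of
#'   them (the usual case: a baseline/comparator pair).
#' @param estimator function taking the (perturbed) list and returning a
#'   numeric vector. Defaults to the Arriaga age contributions plus
#'   total for a pair of mortality schedules, and to the age-by-cause
#'   contributions plus total for a pair of cause schedules.
#' @param config a [sim_config()].
#' @return an object of class `"decomp_uncertainty"` carrying the point
#'   estimates, standard errors, percentile intervals, the replicate
#'   matrix, and failure/truncation counters. Replicates on which the
#'   estimator raises an error are recorded as failed; more than 1%
#'   failures aborts.
#' @examples
#' s1 <- synth_schedule(makeham = c(c = 1e-4, b = 4e-6, theta = 0.122),
#'                      infant = c(a = 0.0075, b = 1.5),
#'                      noise = "poisson", seed = 1)
#' s2 <- synth_schedule(noise = "poisson", seed = 2)
#' mc_se(list(s1, s2), config = sim_config(reps = 200, seed = 9))
#' @export
mc_se <- function(x, estimator = NULL, config = sim_config()) {
  if (!is.list(x) || inherits(x, c("mortality_schedule", "cause_schedule")))
    x <- list(x)
  if (is.null(estimator)) estimator <- default_estimator(x)
  flat <- lapply(x, flatten_rates)
  rates <- unlist(lapply(flat, `[[`, "rates"), use.names = FALSE)
  sds <- sqrt(unlist(lapply(flat, `[[`, "vars"), use.names = FALSE))
  lens <- vapply(flat, function(f) length(f$rates), 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  point <- estimator(x)
  draw_one <- function() {
    r <- stats::rnorm(length(rates), mean = rates, sd = sds)
    tr <- sum(r < 0)
    r[r < 0] <- 0
    scheds <- vector("list", length(x))
    for (k in seq_along(x))
      scheds[[k]] <- inject_rates(x[[k]], r[starts[k]:ends[k]])
    list(scheds = scheds, truncated = tr)
  }
  run_replicates(point, draw_one, estimator, config, "montecarlo")
}

#' Poisson parametric bootstrap
#'
#' Each replicate redraws every age-specific death count from a Poisson
#' distribution whose mean is the observed count, independently per
#' group and population, recomputes the rates over the fixed exposures,
#' and re-evaluates the estimator. Replicates with zero deaths in the
#' open-ended group (where remaining expectancy would be undefined) are
#' flagged as failed and count toward the 1% failure budget.
#'
#' @inheritParams mc_se
#' @param sched1,sched2 [mortality_schedule()] objects with counts,
#'   baseline first.
#' @return a `"decomp_uncertainty"` object, as [mc_se()].
#' @export
poisson_bootstrap <- function(sched1, sched2, estimator = NULL,
                              config = sim_config()) {
  boot_counts(sched1, sched2, estimator, config, family = "poisson")
}

#' Binomial parametric bootstrap
#'
#' As [poisson_bootstrap()], but closed-group death counts are drawn
#' from binomial distributions with success probability `nqx` and number
#' of trials `round(deaths / nqx)` (floored at 1). Because the
#' open-ended group has `q = 1` and so zero binomial variance, its
#' deaths are drawn Poisson with mean the observed count.
#'
#' @inheritParams poisson_bootstrap
#' @return a `"decomp_uncertainty"` object.
#' @export
binomial_bootstrap <- function(sched1, sched2, estimator = NULL,
                               config = sim_config()) {
  boot_counts(sched1, sched2, estimator, config, family = "binomial")
}

boot_counts <- function(sched1, sched2, estimator, config, family) {
  stopifnot(inherits(sched1, "mortality_schedule"),
            inherits(sched2, "mortality_schedule"))
  if (!has_counts(sched1) || !has_counts(sched2))
    stop("the parametric bootstraps need deaths and exposures for both ",
         "populations")
  x <- list(sched1, sched2)
  if (is.null(estimator)) estimator <- default_estimator(x)
  point <- estimator(x)
  K <- nrow(sched1)
  cl <- seq_len(K - 1L)
  if (family == "binomial") {
    prep <- lapply(x, function(s) {
      q <- q_from_m(s$rate[cl], s$ax[cl], s$n[cl])
      list(q = q, size = pmax(1L, as.integer(round(s$deaths[cl] / q))))
    })
  }
  draw_one <- function() {
    scheds <- vector("list", 2L)
    for (k in 1:2) {
      s <- x[[k]]
      d <- if (family == "poisson") {
        stats::rpois(K, s$deaths)
      } else {
        c(stats::rbinom(K - 1L, size = prep[[k]]$size, prob = prep[[k]]$q),
          stats::rpois(1L, s$deaths[K]))
      }
      s$deaths <- d
      s$rate <- d / s$exposure
      scheds[[k]] <- s
    }
    list(scheds = scheds, truncated = 0L)
  }
  run_replicates(point, draw_one, estimator, config,
                 paste0(family, "-bootstrap"))
}

#' Aggregate person-level records into a mortality schedule
#'
#' Helper for micro-data workflows: sums death indicators and
#' person-years by age group.
#'
#' @param records data frame with columns `age` (the age-group start
#'   each person belongs to), `death` (0/1), and optionally `py`
#'   (person-years contributed; defaults to 1 per record).
#' @param grid an [age_grid()] whose starts index the records.
#' @return a [mortality_schedule()] with counts.
#' @export
rates_from_records <- function(records, grid) {
  if (!inherits(grid, "age_grid")) grid <- age_grid(grid)
  py <- if ("py" %in% names(records)) records$py else rep(1, nrow(records))
  f <- factor(records$age, levels = grid$start)
  if (anyNA(f)) stop("records contain ages outside the grid")
  deaths <- as.numeric(tapply(records$death, f, sum, default = 0))
  expo <- as.numeric(tapply(py, f, sum, default = 0))
  mortality_schedule(grid, deaths = deaths, exposure = expo)
}

#' Delete-one jackknife for micro-data
#'
#' Recomputes an estimator on the N subsamples that each omit one
#' record, and estimates the sampling variance as
#' \deqn{\widehat{\mathrm{var}} = \frac{N - 1}{N}
#'   \sum_{j=1}^{N} (\hat\theta_{(j)} - \hat\theta)^2,}
#' with \eqn{\hat\theta} the full-sample estimate. Intended for
#' modest-sized simple random samples of person-level data; no
#' percentile intervals are produced (the replicates are not a sampling
#' distribution), only standard errors and optional normal-theory
#' intervals.
#'
#' @param records data frame of person-level rows; one replicate is
#'   formed per row.
#' @param estimator function of a records data frame returning a numeric
#'   vector (e.g. build rates with [rates_from_records()] and decompose).
#' @param mode replication scheme; only `"delete-one"` is implemented
#'   (survey PSU-level jackknifes need design-specific machinery).
#' @param ci_level optional level for normal-theory intervals.
#' @return a `"decomp_uncertainty"` object (percentile machinery
#'   unused). Replicates on which the estimator fails (e.g. a deleted
#'   record empties an age group) are dropped with a warning and
#'   reported in `failures`.
#' @export
jackknife_microdata <- function(records, estimator, mode = "delete-one",
                                ci_level = NULL) {
  mode <- match.arg(mode, "delete-one")
  N <- nrow(records)
  if (is.null(N) || N < 2L) stop("at least 2 records are required")
  theta <- estimator(records)
  Q <- length(theta)
  reps <- matrix(NA_real_, N, Q, dimnames = list(NULL, names(theta)))
  failures <- 0L
  for (j in seq_len(N)) {
    val <- tryCatch(estimator(records[-j, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(val, "error")) failures <- failures + 1L
    else reps[j, ] <- val
  }
  if (failures) {
    warning(failures, " jackknife replicate(s) failed and were dropped")
    if (failures >= N - 1L) stop("too few successful jackknife replicates")
  }
  ok <- stats::complete.cases(reps)
  n_ok <- sum(ok)
  dev2 <- sweep(reps[ok, , drop = FALSE], 2L, theta)^2
  v <- (n_ok - 1) / n_ok * colSums(dev2)
  se <- sqrt(v)
  lower <- upper <- rep(NA_real_, Q)
  if (!is.null(ci_level)) {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    lower <- theta - z * se
    upper <- theta + z * se
  }
  out <- list(method = "jackknife (delete-one)", estimate = theta, se = se,
              lower = lower, upper = upper, ci_level = ci_level,
              reps = N, seed = NULL, replicates = reps,
              failures = failures, truncated = 0L,
              labels = names(theta))
  class(out) <- "decomp_uncertainty"
  out
}
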