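#' Exact derivatives of the Arriaga decomposition
#'
#' Evaluates, at the observed life-table values, the closed-form partial
#' derivatives of every age contribution \eqn{\Delta_x} with respect to
#' each closed-group survival probability of both populations
#' (\eqn{{}_np_i^1}, \eqn{{}_np_i^2}) and to the open-group death counts
#' (\eqn{D_\omega^1}, \eqn{D_\omega^2}). The derivatives are sparse:
#' baseline probabilities at ages above `x` and comparator probabilities
#' at ages below `x` cannot affect a closed-group contribution, and the
#' open-group contribution depends on comparator mortality only through
#' the open group itself. These zeros are exact, not merely small.
#'
#' The open-group death counts enter through the open-group rate
#' (`m = D / N` with exposure fixed), so schedules must carry counts or
#' exposures.
#'
#' @param lt1,lt2 life tables from [life_table()] on identical grids,
#'   baseline first.
#' @return An object of class `"arriaga_jacobian"`: a list with matrices
#'   `dp1`, `dp2` (rows = decomposition entries, columns = closed-group
#'   probabilities) and vectors `dD1`, `dD2` (derivatives w.r.t. the two
#'   open-group death counts).
#' @seealso [delta_se()] combines the Jacobian with parameter variances.
#' @export
arriaga_jacobian <- function(lt1, lt2) {
  stopifnot(inherits(lt1, "life_table"), inherits(lt2, "life_table"))
  if (!same_grid(attr(lt1, "grid"), attr(lt2, "grid")))
    stop("the two life tables must share the same age grid")
  K <- nrow(lt1)
  cl <- seq_len(K - 1L)
  D1w <- open_deaths(attr(lt1, "schedule"))
  D2w <- open_deaths(attr(lt2, "schedule"))

  l1 <- lt1$l; p1 <- lt1$p; a1 <- lt1$a; L1 <- lt1$L; e1 <- lt1$e
  l2 <- lt2$l; p2 <- lt2$p; a2 <- lt2$a; L2 <- lt2$L; e2 <- lt2$e
  n <- lt1$n

  dp1 <- matrix(0, K, K - 1L)
  dp2 <- matrix(0, K, K - 1L)
  dD1 <- numeric(K)
  dD2 <- numeric(K)

  # coefficient of e2_{x+n} in the closed-group contribution
  coefx <- p2[cl] * l1[cl] - l1[cl + 1L]
  for (x in cl) {
    i <- seq_len(K - 1L)
    below <- i[i < x]
    if (length(below))
      dp1[x, below] <- l1[x] / p1[below] * (L2[x] / l2[x] - L1[x] / l1[x]) +
        e2[x + 1L] / p1[below] * coefx[x]
    dp1[x, x] <- -l1[x] * ((n[x] - a1[x]) + e2[x + 1L])
    dp2[x, x] <- l1[x] * ((n[x] - a2[x]) + e2[x + 1L])
    above <- i[i > x]
    if (length(above))
      dp2[x, above] <- l2[above] / l2[x + 1L] *
        ((n[above] - a2[above]) + e2[above + 1L]) * coefx[x]
    dD2[x] <- -l2[K] / l2[x + 1L] * e2[K] / D2w * coefx[x]
  }
  # open-group contribution: l1_w (e2_w - e1_w)
  dp1[K, ] <- l1[K] / p1[cl] * (e2[K] - e1[K])
  dD1[K] <- l1[K] * e1[K] / D1w
  dD2[K] <- -l1[K] * e2[K] / D2w

  lab <- age_labels(attr(lt1, "grid"))
  dimnames(dp1) <- dimnames(dp2) <- list(lab, lab[cl])
  out <- list(dp1 = dp1, dp2 = dp2, dD1 = dD1, dD2 = dD2,
              grid = attr(lt1, "grid"))
  class(out) <- "arriaga_jacobian"
  out
}

open_deaths <- function(s) {
  K <- nrow(s)
  if (is.finite(s$deaths[K])) return(s$deaths[K])
  if (is.finite(s$exposure[K])) return(s$exposure[K] * s$rate[K])
  stop("open-group death count (or exposure) required for the ",
       "open-group derivatives")
}

#' Count-based variances of the decomposition parameters
#'
#' Sampling variances of the parameters the delta method propagates:
#' binomial variance \eqn{(1 - p)^2 p / D} for each closed-group survival
#' probability, and Poisson variance (equal to the count) for the
#' open-group death count, in both populations. Groups with zero observed
#' deaths contribute zero variance, with a warning.
#'
#' @param sched1,sched2 [mortality_schedule()] objects with death counts,
#'   baseline first.
#' @return An object of class `"param_variances"`: a list with vectors
#'   `var_p1`, `var_p2` (closed groups) and scalars `var_D1`, `var_D2`,
#'   plus a `source` tag.
#' @export
count_variances <- function(sched1, sched2) {
  stopifnot(inherits(sched1, "mortality_schedule"),
            inherits(sched2, "mortality_schedule"))
  if (!has_counts(sched1) || !has_counts(sched2))
    stop("count-based variances need deaths and exposures for both ",
         "populations; for survey-estimated rates supply rate_se and use ",
         "survey_variances()")
  one <- function(s) {
    K <- nrow(s)
    cl <- seq_len(K - 1L)
    p <- 1 - q_from_m(s$rate[cl], s$ax[cl], s$n[cl])
    D <- s$deaths[cl]
    v <- ifelse(D > 0, (1 - p)^2 * p / D, 0)
    if (any(D == 0))
      warning("zero-death group(s) contribute zero variance")
    list(var_p = v, var_D = s$deaths[K])
  }
  v1 <- one(sched1); v2 <- one(sched2)
  out <- list(var_p1 = v1$var_p, var_p2 = v2$var_p,
              var_D1 = v1$var_D, var_D2 = v2$var_D,
              source = "count-based")
  class(out) <- "param_variances"
  out
}

#' Survey-supplied variances of the decomposition parameters
#'
#' Replaces the binomial/Poisson variance forms with squared standard
#' errors estimated by survey software. Rate standard errors are
#' converted to probability standard errors through the exact derivative
#' of the rate-to-probability conversion,
#' \eqn{dq/dm = n / (1 + (n - a) m)^2}; the open-group rate SE is
#' converted to a death-count SE by the fixed exposure.
#'
#' @param sched1,sched2 [mortality_schedule()] objects, baseline first.
#' @param rate_se1,rate_se2 per-group rate standard errors; default to
#'   the schedules' own `rate_se` columns. Required for every group.
#' @return a `"param_variances"` object as in [count_variances()], with
#'   `source = "survey-supplied"`.
#' @export
survey_variances <- function(sched1, sched2,
                             rate_se1 = sched1$rate_se,
                             rate_se2 = sched2$rate_se) {
  one <- function(s, se, who) {
    K <- nrow(s)
    if (length(se) != K || any(!is.finite(se)))
      stop("a rate standard error is required for every age group of ", who)
    if (any(se < 0)) stop("rate standard errors must be >= 0")
    cl <- seq_len(K - 1L)
    se_p <- dq_dm(s$rate[cl], s$ax[cl], s$n[cl]) * se[cl]
    if (!is.finite(s$exposure[K]))
      stop("open-group exposure needed to convert the rate SE to a ",
           "death-count SE for ", who)
    list(var_p = se_p^2, var_D = (s$exposure[K] * se[K])^2)
  }
  v1 <- one(sched1, rate_se1, "population 1")
  v2 <- one(sched2, rate_se2, "population 2")
  out <- list(var_p1 = v1$var_p, var_p2 = v2$var_p,
              var_D1 = v1$var_D, var_D2 = v2$var_D,
              source = "survey-supplied")
  class(out) <- "param_variances"
  out
}

#' Delta-method standard errors for the Arriaga decomposition
#'
#' Combines the exact Jacobian with per-parameter variances in the
#' first-order variance approximation
#' \deqn{\mathrm{var}(\Delta_x) = \sum_i
#'   \Big(\frac{\partial \Delta_x}{\partial \theta_i}\Big)^2
#'   \mathrm{var}(\theta_i)}
#' over all parameters of both populations, assuming independent
#' sampling across age groups and populations. The total's derivative
#' with respect to each parameter is the column sum of the per-age
#' derivatives (parameters are shared across ages), which captures the
#' cross-age covariance induced by shared parameters; the same quadratic
#' form then gives the variance of the total.
#'
#' @param jacobian an [arriaga_jacobian()].
#' @param variances a `"param_variances"` object from
#'   [count_variances()] or [survey_variances()].
#' @param decomposition optional [arriaga_decompose()] result; when
#'   given, normal-theory confidence intervals are attached.
#' @param conf.level confidence level for those intervals.
#' @return An object of class `"decomp_uncertainty"`: per-age and total
#'   standard errors, interval bounds, and a method tag.
#' @export
delta_se <- function(jacobian, variances, decomposition = NULL,
                     conf.level = 0.95) {
  stopifnot(inherits(jacobian, "arriaga_jacobian"),
            inherits(variances, "param_variances"))
  K <- nrow(jacobian$dp1) # decomposition entries
  qf <- function(dp1, dp2, dD1, dD2) {
    drop(dp1^2 %*% variances$var_p1) + drop(dp2^2 %*% variances$var_p2) +
      dD1^2 * variances$var_D1 + dD2^2 * variances$var_D2
  }
  v_age <- qf(jacobian$dp1, jacobian$dp2, jacobian$dD1, jacobian$dD2)
  v_tot <- qf(rbind(colSums(jacobian$dp1)), rbind(colSums(jacobian$dp2)),
              sum(jacobian$dD1), sum(jacobian$dD2))
  se <- sqrt(c(v_age, v_tot))
  names(se) <- c(age_labels(jacobian$grid), "total")
  est <- lower <- upper <- rep(NA_real_, K + 1L)
  if (!is.null(decomposition)) {
    est <- c(decomposition$contribution, attr(decomposition, "total"))
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    lower <- est - z * se
    upper <- est + z * se
  }
  out <- list(method = paste0("delta (", variances$source, ")"),
              estimate = est, se = se, lower = lower, upper = upper,
              ci_level = conf.level, reps = NULL, seed = NULL,
              replicates = NULL, failures = 0L, truncated = 0L,
              labels = names(se))
  class(out) <- "decomp_uncertainty"
  out
}

#' @export
print.decomp_uncertainty <- function(x, digits = 4, ...) {
  cat("Decomposition uncertainty (", x$method, ")\n", sep = "")
  if (!is.null(x$reps))
    cat("  replicates:", x$reps, " seed:", x$seed %||% "none",
        " failed:", x$failures, " truncated draws:", x$truncated, "\n")
  df <- data.frame(quantity = x$labels, estimate = x$estimate, se = x$se,
                   lower = x$lower, upper = x$upper)
  print.data.frame(format(df, digits = digits), row.names = FALSE, ...)
  invisible(x)
}
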