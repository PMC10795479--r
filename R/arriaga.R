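# contribution of each age group to e0(2) - e0(1); lt1, lt2 are lt_core
# lists on identical grids. Closed groups combine the direct effect of
# within-group mortality change with the indirect/interaction effect on
# later survivorship; the open group contributes survivors times the gap
# in remaining expectancy.
arriaga_core <- function(lt1, lt2) {
  K <- length(lt1$m)
  cl <- seq_len(K - 1L)
  lnext1 <- lt1$l[cl + 1L]
  d <- numeric(K)
  d[cl] <- lt1$l[cl] * (lt2$L[cl] / lt2$l[cl] - lt1$L[cl] / lt1$l[cl]) +
    lt2$e[cl + 1L] * (lt2$p[cl] * lt1$l[cl] - lnext1)
  d[K] <- lt1$l[K] * (lt2$e[K] - lt1$e[K])
  d
}

#' Arriaga age decomposition of a life-expectancy difference
#'
#' Attributes the difference in life expectancy at birth between two
#' populations to age groups. For closed groups the contribution is
#' \deqn{\Delta_x = \frac{l_x^1}{l_0^1}\Big(\frac{{}_nL_x^2}{l_x^2}
#'   - \frac{{}_nL_x^1}{l_x^1}\Big)
#'   + \frac{e_{x+n}^2}{l_0^1}\big({}_np_x^2 l_x^1 - l_{x+n}^1\big),}
#' and for the open-ended group
#' \eqn{\Delta_\omega = (l_\omega^1/l_0^1)(e_\omega^2 - e_\omega^1)}.
#' The contributions sum exactly to \eqn{e_0^2 - e_0^1}: population 1 is
#' the baseline, population 2 the comparator.
#'
#' @param lt1,lt2 life tables from [life_table()] on identical grids;
#'   `lt1` is the baseline.
#' @return An object of class `"arriaga_decomposition"`: a data frame
#'   with columns `age`, `n`, `contribution`, with the total, the two
#'   e0 values and the grid as attributes.
#' @seealso [arriaga()] for the full interface with standard errors.
#' @export
arriaga_decompose <- function(lt1, lt2) {
  stopifnot(inherits(lt1, "life_table"), inherits(lt2, "life_table"))
  if (!same_grid(attr(lt1, "grid"), attr(lt2, "grid")))
    stop("the two life tables must share the same age grid")
  d <- arriaga_core(lt1, lt2)
  out <- data.frame(age = lt1$age, n = lt1$n, contribution = d)
  class(out) <- c("arriaga_decomposition", "data.frame")
  attr(out, "grid") <- attr(lt1, "grid")
  attr(out, "e0") <- c(pop1 = lt1$e[1], pop2 = lt2$e[1])
  attr(out, "total") <- sum(d)
  out
}

#' @export
print.arriaga_decomposition <- function(x, digits = 4, ...) {
  e0 <- attr(x, "e0")
  cat("Arriaga decomposition of e0 difference (baseline -> comparator)\n")
  cat(sprintf("e0: %.4f -> %.4f, difference %.4f years\n",
              e0[1], e0[2], attr(x, "total")))
  df <- data.frame(age = age_labels(attr(x, "grid")),
                   contribution = round(x$contribution, digits))
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' Split an Arriaga age decomposition by cause of death
#'
#' Distributes each age group's contribution across causes of death in
#' proportion to the cause-specific rate changes:
#' \deqn{\Delta_{x,i} = \Delta_x \,
#'   \frac{m_{x,i}^2 - m_{x,i}^1}{m_x^2 - m_x^1}.}
#' The cause contributions sum across causes to the age contribution.
#' When the all-cause rate change in a group is numerically zero the
#' ratio is undefined: if the group's age contribution is also (near)
#' zero all causes get 0; otherwise an error is raised rather than
#' returning unstable ratios.
#'
#' @param age_result an [arriaga_decompose()] result for the two
#'   populations underlying `causes1` and `causes2`.
#' @param causes1,causes2 [cause_schedule()] objects for the baseline and
#'   comparator populations, with identical cause sets.
#' @return An object of class `"cause_decomposition"`: a data frame with
#'   columns `age`, `n`, then one column per cause; the age contributions
#'   are kept as an attribute.
#' @export
cause_decompose <- function(age_result, causes1, causes2) {
  stopifnot(inherits(age_result, "arriaga_decomposition"),
            inherits(causes1, "cause_schedule"),
            inherits(causes2, "cause_schedule"))
  if (!identical(causes1$causes, causes2$causes))
    stop("the two cause schedules must share the same causes in the same order")
  g <- attr(age_result, "grid")
  if (!same_grid(g, sched_grid(causes1$schedule)) ||
      !same_grid(g, sched_grid(causes2$schedule)))
    stop("cause schedules must be on the decomposition's age grid")
  dxi <- cause_split(age_result$contribution,
                     causes1$schedule$rate, causes2$schedule$rate,
                     causes1$rate, causes2$rate)
  colnames(dxi) <- causes1$causes
  out <- data.frame(age = age_result$age, n = age_result$n)
  out <- cbind(out, as.data.frame(dxi))
  class(out) <- c("cause_decomposition", "data.frame")
  attr(out, "grid") <- g
  attr(out, "age_contribution") <- age_result$contribution
  attr(out, "causes") <- causes1$causes
  out
}

# core of the cause split; m1, m2 all-cause rate vectors, cm1, cm2
# age x cause rate matrices
cause_split <- function(dx, m1, m2, cm1, cm2) {
  dm <- m2 - m1
  dxi <- matrix(0, nrow = length(dx), ncol = ncol(cm1))
  ok <- abs(dm) >= 1e-15
  dxi[ok, ] <- dx[ok] * (cm2[ok, , drop = FALSE] - cm1[ok, , drop = FALSE]) / dm[ok]
  if (any(!ok & abs(dx) > 1e-10))
    stop("all-cause rate change is numerically zero in a group with a ",
         "non-zero contribution; the cause split is undefined there")
  dxi
}

#' @export
print.cause_decomposition <- function(x, digits = 4, ...) {
  cat("Arriaga decomposition by age and cause of death (years of e0 difference)\n")
  df <- as.data.frame(x)
  df$age <- age_labels(attr(x, "grid"))
  df$n <- NULL
  print.data.frame(df, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Arriaga decomposition with standard errors
#'
#' The package's central fitting function. Builds abridged life tables
#' for two mortality schedules, decomposes the difference in life
#' expectancy at birth into additive age-group contributions (and
#' optionally into age-by-cause contributions), and attaches standard
#' errors and confidence intervals by the requested route:
#'
#' \describe{
#'   \item{`"delta"`}{analytic delta-method variance with exact
#'     closed-form derivatives ([delta_se()]); binomial variances for the
#'     closed-group survival probabilities and a Poisson variance for the
#'     open-group death count, or survey-supplied rate standard errors
#'     when both schedules carry `rate_se`.}
#'   \item{`"montecarlo"`}{normal perturbation of the death rates with
#'     variance `rate / exposure` (or `rate_se^2`), [mc_se()].}
#'   \item{`"poisson"`, `"binomial"`}{parametric bootstraps of the death
#'     counts, [poisson_bootstrap()] and [binomial_bootstrap()].}
#' }
#'
#' @param pop1,pop2 [mortality_schedule()] objects on the same grid;
#'   `pop1` is the baseline whose e0 is subtracted.
#' @param causes1,causes2 optional [cause_schedule()] objects for a
#'   cause-of-death split.
#' @param se standard-error method, or `"none"`.
#' @param conf.level confidence level for the intervals.
#' @param reps replicates for the resampling methods.
#' @param seed integer seed for the resampling methods (required there
#'   for reproducibility).
#' @return An object of class `"arriaga"` with components `decomposition`
#'   (age table with contribution, and se/lower/upper when requested),
#'   `total`, `e0`, `lifetables`, `cause` (optional
#'   [cause_decompose()] result), `uncertainty` (the full
#'   [summarize_replicates()]-style result object) and `call`. Methods:
#'   `print`, `summary`, `coef`, `confint`, `plot`.
#' @examples
#' s1 <- synth_schedule(makeham = c(c = 1e-4, b = 4e-6, theta = 0.122),
#'                      infant = c(a = 0.0075, b = 1.5),
#'                      noise = "poisson", seed = 1)
#' s2 <- synth_schedule(noise = "poisson", seed = 2)
#' fit <- arriaga(s1, s2, se = "delta")
#' fit
#' coef(fit)
#' confint(fit)
#' @export
arriaga <- function(pop1, pop2, causes1 = NULL, causes2 = NULL,
                    se = c("none", "delta", "montecarlo", "poisson", "binomial"),
                    conf.level = 0.95, reps = 1000, seed = NULL) {
  se <- match.arg(se)
  stopifnot(inherits(pop1, "mortality_schedule"),
            inherits(pop2, "mortality_schedule"))
  lt1 <- life_table(pop1)
  lt2 <- life_table(pop2)
  dec <- arriaga_decompose(lt1, lt2)
  cause <- NULL
  if (!is.null(causes1) || !is.null(causes2)) {
    if (is.null(causes1) || is.null(causes2))
      stop("supply cause schedules for both populations or neither")
    cause <- cause_decompose(dec, causes1, causes2)
  }

  unc <- NULL
  if (se == "delta") {
    jac <- arriaga_jacobian(lt1, lt2)
    vars <- if (all(is.finite(pop1$rate_se)) && all(is.finite(pop2$rate_se)))
      survey_variances(pop1, pop2) else count_variances(pop1, pop2)
    unc <- delta_se(jac, vars, decomposition = dec, conf.level = conf.level)
  } else if (se != "none") {
    cfg <- sim_config(reps = reps, seed = seed, ci_level = conf.level)
    unc <- switch(se,
      montecarlo = mc_se(list(pop1, pop2), config = cfg),
      poisson    = poisson_bootstrap(pop1, pop2, config = cfg),
      binomial   = binomial_bootstrap(pop1, pop2, config = cfg))
  }

  tab <- data.frame(age = dec$age, n = dec$n, contribution = dec$contribution)
  if (!is.null(unc)) {
    K <- nrow(tab)
    tab$se <- unc$se[seq_len(K)]
    tab$lower <- unc$lower[seq_len(K)]
    tab$upper <- unc$upper[seq_len(K)]
  }
  fit <- list(decomposition = tab,
              total = attr(dec, "total"),
              e0 = attr(dec, "e0"),
              lifetables = list(pop1 = lt1, pop2 = lt2),
              cause = cause,
              uncertainty = unc,
              se_method = se,
              conf.level = conf.level,
              call = match.call())
  class(fit) <- "arriaga"
  fit
}

#' @export
print.arriaga <- function(x, digits = 4, ...) {
  cat("Arriaga decomposition of life expectancy at birth\n")
  cat(sprintf("  e0 baseline:   %8.4f\n  e0 comparator: %8.4f\n  difference:    %8.4f years\n",
              x$e0[1], x$e0[2], x$total))
  if (x$se_method != "none")
    cat("  standard errors:", x$se_method,
        if (!is.null(x$uncertainty$reps)) paste0("(", x$uncertainty$reps, " replicates)"),
        "\n")
  df <- x$decomposition
  df$age <- age_labels(attr(x$lifetables$pop1, "grid"))
  df$n <- NULL
  print.data.frame(format(df, digits = digits), row.names = FALSE, ...)
  tot <- c(contribution = x$total)
  if (!is.null(x$uncertainty)) {
    nt <- length(x$uncertainty$se)
    tot <- c(tot, se = x$uncertainty$se[nt],
             lower = x$uncertainty$lower[nt], upper = x$uncertainty$upper[nt])
  }
  cat("total:", paste(names(tot), format(unname(tot), digits = digits),
                      sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.arriaga <- function(object, ...) {
  stats::setNames(object$decomposition$contribution,
                  age_labels(attr(object$lifetables$pop1, "grid")))
}

#' @export
confint.arriaga <- function(object, parm, level = NULL, ...) {
  if (is.null(object$uncertainty))
    stop("fit with a standard-error method to obtain confidence intervals")
  if (!is.null(level) && abs(level - object$conf.level) > 1e-12)
    stop("intervals were computed at level ", object$conf.level,
         "; refit to change the level")
  lab <- c(age_labels(attr(object$lifetables$pop1, "grid")), "total")
  ci <- cbind(lower = object$uncertainty$lower, upper = object$uncertainty$upper)
  rownames(ci) <- lab
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.arriaga <- function(object, ...) {
  out <- object
  out$share <- object$decomposition$contribution / object$total
  class(out) <- "summary.arriaga"
  out
}

#' @export
print.summary.arriaga <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "arriaga"
  print(y, digits = digits, ...)
  u <- x$uncertainty
  if (!is.null(u)) {
    cat("\nUncertainty method:", u$method, "\n")
    if (!is.null(u$reps)) cat("  replicates:", u$reps,
                              " failed:", u$failures %||% 0,
                              " truncated draws:", u$truncated %||% 0, "\n")
    if (!is.null(u$seed)) cat("  seed:", u$seed, "\n")
  }
  big <- order(abs(x$decomposition$contribution), decreasing = TRUE)[1:3]
  lab <- age_labels(attr(x$lifetables$pop1, "grid"))
  cat("\nLargest contributions:",
      paste(lab[big], "=", round(x$decomposition$contribution[big], digits),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot an Arriaga decomposition
#'
#' Bar chart of age-group contributions to the life-expectancy
#' difference, with confidence-interval whiskers when the fit carries
#' uncertainty.
#'
#' @param x an [arriaga()] fit.
#' @param ... further arguments passed to [graphics::barplot()].
#' @export
plot.arriaga <- function(x, ...) {
  lab <- age_labels(attr(x$lifetables$pop1, "grid"))
  v <- x$decomposition$contribution
  ylim <- range(0, v, x$decomposition$upper, x$decomposition$lower, na.rm = TRUE)
  bp <- graphics::barplot(v, names.arg = lab, las = 2, ylim = ylim * 1.05,
                          ylab = "contribution to e0 difference (years)", ...)
  if (!is.null(x$decomposition$se))
    graphics::arrows(bp, x$decomposition$lower, bp, x$decomposition$upper,
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0)
  invisible(bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
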