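#' Death probability from a central death rate
#'
#' Converts an age-specific central death rate `nmx` to the conditional
#' probability of dying in the interval, `nqx`, by the standard abridged
#' life-table relation
#' \deqn{q = \frac{n\,m}{1 + (n - a)\,m},}
#' where `n` is the interval width and `a` the average person-years lived
#' in the interval by decedents. Open-ended intervals (`n = Inf`) get
#' `q = 1`. Values that would exceed 1 (possible for extreme synthetic
#' inputs) are clamped to 1 with a warning.
#'
#' @param m central death rate(s), >= 0.
#' @param ax average person-years lived by decedents, 0 < ax <= n for
#'   closed intervals; ignored for open intervals.
#' @param n interval width(s) in years; `Inf` marks an open interval.
#' @return probability (vector) of dying in the interval.
#' @examples
#' q_from_m(0.007655, 0.074435, 1)   # infant group
#' q_from_m(0.061530, 2.5, 5)        # 80-84
#' @export
q_from_m <- function(m, ax, n) {
  stopifnot(all(m >= 0))
  q <- ifelse(is.infinite(n), 1, n * m / (1 + (n - ax) * m))
  if (any(q > 1)) {
    warning("q exceeded 1 in ", sum(q > 1), " group(s); clamped to 1")
    q <- pmin(q, 1)
  }
  q
}

# exact derivative dq/dm of the conversion above (closed intervals)
dq_dm <- function(m, ax, n) n / (1 + (n - ax) * m)^2

# minimal life-table engine shared by the fitting path and the resampling
# engines; no validation, no classes. m, a, n are equal-length vectors with
# the open group last (n = Inf).
lt_core <- function(m, a, n) {
  K <- length(m)
  cl <- seq_len(K - 1L)
  q <- c(n[cl] * m[cl] / (1 + (n[cl] - a[cl]) * m[cl]), 1)
  q[q > 1] <- 1
  p <- 1 - q
  # sequential double products (not cumprod, whose long-double accumulator
  # would break the exact identity l[x+1] == l[x] * p[x] that the
  # decomposition's zero-under-identity property relies on)
  l <- numeric(K)
  l[1L] <- 1
  for (k in cl) l[k + 1L] <- l[k] * p[k]
  lnext <- c(l[-1L], 0)
  L <- c(n[cl] * lnext[cl] + a[cl] * (l[cl] - lnext[cl]), l[K] / m[K])
  T <- rev(cumsum(rev(L)))
  list(q = q, p = p, l = l, L = L, T = T, e = T / l, m = m, a = a, n = n)
}

#' Build an abridged period life table
#'
#' Constructs the standard columns of an abridged life table (radix 1)
#' from a mortality schedule: probabilities of dying `nqx` via
#' [q_from_m()], survivorship `lx` as the cumulative product of survival
#' probabilities, person-years lived `nLx = n l(x+n) + a (lx - l(x+n))`
#' for closed groups and `lx / m` for the open group, person-years above
#' `x` (`Tx`) and remaining life expectancy `ex = Tx / lx`.
#'
#' @param schedule a [mortality_schedule()] whose final group is
#'   open-ended with a strictly positive rate.
#' @return An object of class `"life_table"`: a data frame with columns
#'   `age, n, m, a, q, p, l, L, T, e`; the input schedule is kept as an
#'   attribute.
#' @examples
#' s <- synth_schedule(seed = 1)
#' life_table(s)
#' @export
life_table <- function(schedule) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  grid <- sched_grid(schedule)
  if (!is_open(grid))
    stop("life tables require an open-ended final age group")
  K <- nrow(schedule)
  if (schedule$rate[K] <= 0)
    stop("open-group death rate must be > 0 (open-group expectancy undefined)")
  lt <- lt_core(schedule$rate, schedule$ax, schedule$n)
  out <- data.frame(age = schedule$age, n = schedule$n,
                    m = lt$m, a = lt$a, q = lt$q, p = lt$p,
                    l = lt$l, L = lt$L, T = lt$T, e = lt$e)
  class(out) <- c("life_table", "data.frame")
  attr(out, "grid") <- grid
  attr(out, "schedule") <- schedule
  out
}

#' @export
print.life_table <- function(x, digits = 6, ...) {
  cat("Abridged life table (radix 1), e0 =", format(x$e[1], digits = 6), "\n")
  df <- as.data.frame(x)
  df$age <- age_labels(attr(x, "grid"))
  print.data.frame(df, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Delta-method variance of life expectancy at birth
#'
#' Analytic sampling variance of `e0` for a single population, obtained
#' by propagating binomial variances of the survival probabilities
#' (`var(p) = (1 - p)^2 p / D` for closed groups) and a Poisson variance
#' for the open-group death count (`var(D) = D`) through the exact
#' derivatives of `e0`. Serves as an independent oracle for the total of
#' the Arriaga decomposition: the decomposition total is `e0(2) - e0(1)`,
#' so its delta-method variance must equal the sum of the two
#' single-population variances.
#'
#' @param schedule a [mortality_schedule()] with death counts.
#' @return the approximate sampling variance of `e0` (scalar).
#' @seealso [delta_se()], [count_variances()]
#' @export
e0_var_delta <- function(schedule) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  if (!has_counts(schedule))
    stop("e0_var_delta requires death counts and exposures")
  lt <- lt_core(schedule$rate, schedule$ax, schedule$n)
  K <- length(lt$m)
  cl <- seq_len(K - 1L)
  D <- schedule$deaths
  # d e0 / d p_i = l_i ((n_i - a_i) + e_{i+n})   (radix 1)
  de_dp <- lt$l[cl] * ((lt$n[cl] - lt$a[cl]) + lt$e[cl + 1L])
  var_p <- ifelse(D[cl] > 0, (1 - lt$p[cl])^2 * lt$p[cl] / D[cl], 0)
  if (any(D[cl] == 0))
    warning("group(s) with zero deaths contribute zero variance")
  # d e0 / d D_omega = - l_omega e_omega / D_omega  (through m = D / N)
  de_dD <- -lt$l[K] * lt$e[K] / D[K]
  var_D <- D[K]
  sum(de_dp^2 * var_p) + de_dD^2 * var_D
}
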