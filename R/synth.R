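#' Synthetic abridged mortality schedule from a smooth hazard
#'
#' Generates a mortality schedule whose true age-specific rates are
#' exposure-weighted averages of a parametric hazard
#' \deqn{\mu(x) = c + b\,e^{\theta x} + A\,e^{-B x},}
#' a Gompertz--Makeham law plus an optional infant-mortality term (the
#' Siler model). Group rates are computed as
#' \eqn{\int \mu S \,dx / \int S \,dx} over each interval with
#' \eqn{S(x) = \exp(-\int_0^x \mu)}, evaluated on a fine quadrature grid;
#' the open group is integrated up to age 130, beyond which survivorship
#' is negligible for any human-scale hazard. Death counts are then either
#' the exact expectations (`noise = "none"`), Poisson draws with mean
#' `exposure * rate`, or binomial draws with probability `nqx` and trials
#' `round(deaths / nqx)`.
#'
#' The defaults emulate the study conditions the package's fixtures
#' represent: low-mortality female schedules on the conventional
#' 0, 1--4, 5--9, ..., 85+ grid with exposures of a 50% sample of a
#' population of a few million. The default hazard gives a life
#' expectancy near 84.6 years (a recent-period low-mortality schedule);
#' a higher-mortality companion set such as `makeham = c(c = 1e-4,
#' b = 4e-6, theta = 0.122)`, `infant = c(a = 0.0075, b = 1.5)` (e0 near
#' 79.1) makes a realistic baseline for decomposition pairs.
#'
#' @param grid an [age_grid()]; default 0, 1--4, 5--9, ..., 85+.
#' @param exposure person-years per group; default a realistic
#'   urban-region female age structure totalling about 6 million.
#' @param makeham named vector `c(c=, b=, theta=)` of baseline, level and
#'   slope of the Gompertz--Makeham part (per-year hazard units).
#' @param infant named vector `c(a=, b=)` of the infant term
#'   `a * exp(-b x)`; set `a = 0` to disable.
#' @param noise `"none"` (deaths equal their expectation), `"poisson"`,
#'   or `"binomial"`.
#' @param seed optional integer seed; with a fixed seed the schedule is
#'   reproducible draw-for-draw.
#' @return a [mortality_schedule()] with deaths, exposure and default
#'   `ax`; the noiseless group rates are attached as attribute
#'   `"true_rate"`.
#' @examples
#' s <- synth_schedule(seed = 42, noise = "poisson")
#' attr(s, "true_rate") - s$rate   # sampling noise around the true rates
#' @export
synth_schedule <- function(grid = age_grid(c(0, 1, seq(5, 85, by = 5))),
                           exposure = NULL,
                           makeham = c(c = 5e-5, b = 1.7e-6, theta = 0.125),
                           infant = c(a = 0.0035, b = 1.5),
                           noise = c("none", "poisson", "binomial"),
                           seed = NULL) {
  noise <- match.arg(noise)
  if (!inherits(grid, "age_grid")) grid <- age_grid(grid)
  K <- nrow(grid)
  if (is.null(exposure)) {
    if (K != 19L)
      stop("default exposures are defined for the standard 19-group grid; ",
           "supply 'exposure' for other grids")
    exposure <- c(80, 320, 400, 400, 400, 430, 450, 440, 420, 400,
                  390, 380, 370, 340, 300, 240, 170, 110, 90) * 1000
  }
  if (length(exposure) != K || any(exposure <= 0))
    stop("'exposure' must be positive with one value per age group")

  mu <- function(x) {
    makeham[["c"]] + makeham[["b"]] * exp(makeham[["theta"]] * x) +
      infant[["a"]] * exp(-infant[["b"]] * x)
  }
  top <- 130
  h <- 1 / 64
  xs <- seq(0, top, by = h)
  mus <- mu(xs)
  if (any(mus < 0))
    stop("hazard parameters yield a negative hazard")
  # survivorship by trapezoidal cumulative hazard
  H <- c(0, cumsum((mus[-1L] + mus[-length(mus)]) / 2 * h))
  S <- exp(-H)
  cum_muS <- c(0, cumsum((mus[-1L] * S[-1L] + mus[-length(mus)] * S[-length(S)]) / 2 * h))
  cum_S <- c(0, cumsum((S[-1L] + S[-length(S)]) / 2 * h))
  at <- function(v, x) v[round(x / h) + 1L]
  up <- pmin(grid$start + grid$n, top)
  rate <- (at(cum_muS, up) - at(cum_muS, grid$start)) /
          (at(cum_S, up) - at(cum_S, grid$start))

  ax <- default_ax(grid, rate)
  expect <- exposure * rate
  if (!is.null(seed)) set.seed(seed)
  deaths <- switch(noise,
    none = expect,
    poisson = stats::rpois(K, expect),
    binomial = {
      q <- q_from_m(rate, ax, grid$n)
      cl <- seq_len(K - 1L)
      d <- numeric(K)
      d[cl] <- stats::rbinom(K - 1L, size = pmax(1L, as.integer(round(expect[cl] / q[cl]))),
                             prob = q[cl])
      d[K] <- stats::rpois(1L, expect[K])
      d
    })
  s <- mortality_schedule(grid, deaths = deaths, exposure = exposure, ax = ax)
  attr(s, "true_rate") <- rate
  s
}
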