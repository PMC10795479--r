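#' Abridged age grid
#'
#' Defines the age groups of an abridged mortality schedule: group lower
#' bounds, widths in years, and whether the final group is open-ended
#' (no upper bound). The usual demographic grid is 0, 1--4, 5--9, ...,
#' 80--84, 85+.
#'
#' @param starts numeric vector of age-group lower bounds in years,
#'   strictly increasing.
#' @param widths group widths in years. Defaults to `diff(starts)`
#'   followed by `Inf` when `open = TRUE`; when supplied, contiguity
#'   (`starts[k + 1] == starts[k] + widths[k]`) is enforced for closed
#'   groups. Age groups are half-open intervals `[start, start + n)`;
#'   the open group is `[start, Inf)`.
#' @param open logical; is the final group open-ended? Only the last
#'   group may be open.
#' @return An object of class `"age_grid"`: a data frame with columns
#'   `start` and `n` (the open group has `n = Inf`).
#' @examples
#' age_grid(c(0, 1, seq(5, 85, by = 5)))
#' @export
age_grid <- function(starts, widths = NULL, open = TRUE) {
  starts <- as.numeric(starts)
  K <- length(starts)
  if (K < 2L) stop("an age grid needs at least two groups")
  if (any(!is.finite(starts)) || any(diff(starts) <= 0))
    stop("age-group starts must be finite and strictly increasing")
  if (is.null(widths)) {
    widths <- c(diff(starts), if (open) Inf else NA_real_)
    if (!open)
      stop("width of the final closed group must be supplied via 'widths'")
  } else {
    widths <- as.numeric(widths)
    if (length(widths) != K)
      stop("'widths' must have one entry per age group")
    if (open && !is.infinite(widths[K])) widths[K] <- Inf
    closed <- seq_len(K - if (open) 1L else 0L)
    if (any(starts[-K] + widths[-K] != starts[-1L]))
      stop("age groups must be contiguous: starts[k+1] == starts[k] + widths[k]")
    if (any(widths[closed] <= 0) || any(!is.finite(widths[closed])))
      stop("closed-group widths must be positive and finite")
  }
  g <- data.frame(start = starts, n = widths)
  class(g) <- c("age_grid", "data.frame")
  attr(g, "open") <- open
  g
}

#' @export
print.age_grid <- function(x, ...) {
  lab <- age_labels(x)
  cat("Abridged age grid:", nrow(x), "groups:",
      paste(lab[c(1, 2)], collapse = ", "), "...",
      lab[nrow(x)], "\n")
  invisible(x)
}

age_labels <- function(grid) {
  ifelse(is.infinite(grid$n),
         paste0(grid$start, "+"),
         ifelse(grid$n == 1, as.character(grid$start),
                paste0(grid$start, "-", grid$start + grid$n - 1)))
}

is_open <- function(grid) isTRUE(attr(grid, "open"))

same_grid <- function(g1, g2) {
  nrow(g1) == nrow(g2) &&
    all(g1$start == g2$start) &&
    all(g1$n == g2$n | (is.infinite(g1$n) & is.infinite(g2$n)))
}

#' Default average person-years lived by decedents
#'
#' The conventional fill-in used when a schedule does not supply nax:
#' half the interval width for closed groups, except under-five ages on a
#' grid starting at 0, where a0 = 0.07 + 1.7 m0 (capped to (0, 1)) and
#' a(1-4) = 1.5. The open group carries no nax.
#'
#' @param grid an [age_grid()].
#' @param m age-specific death rates (used only for the infant group).
#' @return numeric vector of nax values, `NA` for the open group.
#' @export
default_ax <- function(grid, m) {
  K <- nrow(grid)
  ax <- grid$n / 2
  ax[is.infinite(grid$n)] <- NA_real_
  if (grid$start[1] == 0 && grid$n[1] == 1)
    ax[1] <- min(max(0.07 + 1.7 * m[1], .Machine$double.eps), 1)
  if (K >= 2 && grid$start[2] == 1 && grid$n[2] == 4 && is.finite(grid$n[2]))
    ax[2] <- 1.5
  ax
}

#' Mortality schedule for one population
#'
#' Bundles an abridged age grid with deaths, person-years of exposure,
#' death rates `nmx`, average person-years lived by decedents `nax`, and
#' (optionally, for survey-estimated rates) per-group standard errors of
#' the rates. Either `deaths` + `exposure` or `rate` must be supplied;
#' rates are computed as deaths/exposure when absent, and missing `ax`
#' values are filled by [default_ax()].
#'
#' @param grid an [age_grid()], or a numeric vector of group starts
#'   (interpreted as an open-ended grid).
#' @param deaths death counts per group, all >= 0. Non-integer values are
#'   accepted (e.g. weighted counts).
#' @param exposure person-years of exposure per group, all > 0.
#' @param rate central death rates `nmx` per group. When counts are also
#'   given, must equal deaths/exposure to 1e-12 relative.
#' @param ax average person-years lived in the interval by those dying in
#'   it; must satisfy 0 < ax <= n for closed groups. Ignored (and stored
#'   as `NA`) for the open group. `NA` entries are filled by the default
#'   rule.
#' @param rate_se optional standard errors of the rates (survey mode),
#'   all >= 0.
#' @return An object of class `"mortality_schedule"`: a data frame with
#'   columns `age`, `n`, `deaths`, `exposure`, `rate`, `ax`, `rate_se`
#'   and the grid stored as an attribute.
#' @seealso [read_schedule()], [synth_schedule()], [life_table()]
#' @examples
#' sched <- mortality_schedule(
#'   age_grid(c(0, 1, seq(5, 85, 5))),
#'   rate = c(0.007655, 0.000433, 0.000185, 0.000224, 0.000399, 0.000467,
#'            0.000538, 0.000752, 0.001069, 0.001541, 0.002628, 0.004234,
#'            0.006295, 0.010252, 0.015119, 0.023492, 0.037778, 0.061530,
#'            0.151531))
#' @export
mortality_schedule <- function(grid, deaths = NULL, exposure = NULL,
                               rate = NULL, ax = NULL, rate_se = NULL) {
  if (!inherits(grid, "age_grid")) grid <- age_grid(grid)
  K <- nrow(grid)
  chk_len <- function(v, nm) {
    if (!is.null(v) && length(v) != K)
      stop("'", nm, "' must have one value per age group (", K, ")")
    if (!is.null(v)) as.numeric(v) else NULL
  }
  deaths <- chk_len(deaths, "deaths")
  exposure <- chk_len(exposure, "exposure")
  rate <- chk_len(rate, "rate")
  ax <- chk_len(ax, "ax")
  rate_se <- chk_len(rate_se, "rate_se")

  have_counts <- !is.null(deaths) && !is.null(exposure)
  if (!have_counts && is.null(rate))
    stop("supply either deaths + exposure, or rate")
  if (!is.null(exposure)) {
    bad <- which(!(exposure > 0))
    if (length(bad))
      stop("exposure must be > 0; offending row(s): ",
           paste(bad, " (age ", grid$start[bad], ")", sep = "", collapse = ", "))
  }
  if (!is.null(deaths)) {
    bad <- which(deaths < 0 | !is.finite(deaths))
    if (length(bad))
      stop("deaths must be finite and >= 0; offending row(s): ",
           paste(bad, " (age ", grid$start[bad], ")", sep = "", collapse = ", "))
  }
  if (have_counts) {
    mx <- deaths / exposure
    if (!is.null(rate)) {
      rel <- abs(rate - mx) / pmax(abs(mx), .Machine$double.xmin)
      bad <- which(rel > 1e-12 & mx > 0)
      if (length(bad))
        stop("rate inconsistent with deaths/exposure at row(s): ",
             paste(bad, collapse = ", "))
    }
    rate <- mx
  }
  if (any(rate < 0 | !is.finite(rate)))
    stop("rates must be finite and >= 0")
  if (!is.null(rate_se) && any(rate_se < 0, na.rm = TRUE))
    stop("rate_se must be >= 0")

  if (is.null(ax)) ax <- rep(NA_real_, K)
  fill <- is.na(ax)
  if (any(fill)) ax[fill] <- default_ax(grid, rate)[fill]
  ax[is.infinite(grid$n)] <- NA_real_
  closed <- is.finite(grid$n)
  if (any(ax[closed] <= 0 | ax[closed] > grid$n[closed]))
    stop("ax must satisfy 0 < ax <= n for closed groups")

  zero <- closed & rate == 0
  if (any(zero))
    warning("zero deaths observed in closed group(s) ",
            paste(age_labels(grid)[zero], collapse = ", "),
            ": no method assigns positive variance to a group with zero ",
            "observed deaths; its variance contribution will be 0")

  s <- data.frame(age = grid$start, n = grid$n,
                  deaths = if (is.null(deaths)) NA_real_ else deaths,
                  exposure = if (is.null(exposure)) NA_real_ else exposure,
                  rate = rate, ax = ax,
                  rate_se = if (is.null(rate_se)) NA_real_ else rate_se)
  class(s) <- c("mortality_schedule", "data.frame")
  attr(s, "grid") <- grid
  s
}

#' @export
print.mortality_schedule <- function(x, digits = 6, ...) {
  cat("Mortality schedule:", nrow(x), "age groups (",
      age_labels(attr(x, "grid"))[1], "...",
      age_labels(attr(x, "grid"))[nrow(x)], ")\n")
  if (has_counts(x))
    cat("Total deaths:", format(sum(x$deaths), big.mark = ","),
        " person-years:", format(sum(x$exposure), big.mark = ","), "\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE, ...)
  invisible(x)
}

has_counts <- function(s) all(is.finite(s$deaths)) && all(is.finite(s$exposure))

sched_grid <- function(s) attr(s, "grid")

#' Cause-of-death schedule
#'
#' Attaches cause-specific death counts to a mortality schedule. Cause
#' counts must sum across causes to the schedule's total deaths in every
#' age group. Cause-specific rates are deaths over the (all-cause)
#' exposure.
#'
#' @param schedule a [mortality_schedule()] carrying deaths and exposure.
#' @param cause_deaths numeric matrix, age groups x causes.
#' @param causes optional character vector of cause labels; defaults to
#'   the matrix column names or `cause1`, `cause2`, ...
#' @return An object of class `"cause_schedule"`: a list with the parent
#'   `schedule`, the `deaths` matrix, the cause `rate` matrix
#'   (deaths / exposure), and `causes`.
#' @export
cause_schedule <- function(schedule, cause_deaths, causes = NULL) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  if (!has_counts(schedule))
    stop("cause schedules require a schedule with deaths and exposure")
  cause_deaths <- as.matrix(cause_deaths)
  if (nrow(cause_deaths) != nrow(schedule))
    stop("cause_deaths must have one row per age group")
  if (is.null(causes))
    causes <- colnames(cause_deaths)
  if (is.null(causes))
    causes <- paste0("cause", seq_len(ncol(cause_deaths)))
  if (length(causes) != ncol(cause_deaths))
    stop("one label per cause required")
  if (any(cause_deaths < 0))
    stop("cause-specific deaths must be >= 0")
  tot <- rowSums(cause_deaths)
  bad <- which(abs(tot - schedule$deaths) > 1e-9)
  if (length(bad))
    stop("cause-specific deaths do not sum to total deaths at row(s): ",
         paste(bad, collapse = ", "))
  dimnames(cause_deaths) <- list(age_labels(sched_grid(schedule)), causes)
  out <- list(schedule = schedule,
              deaths = cause_deaths,
              rate = cause_deaths / schedule$exposure,
              causes = causes)
  class(out) <- "cause_schedule"
  out
}

#' @export
print.cause_schedule <- function(x, digits = 6, ...) {
  cat("Cause-of-death schedule:", nrow(x$deaths), "age groups x",
      length(x$causes), "causes (", paste(x$causes, collapse = ", "), ")\n")
  print(round(x$deaths, 2))
  invisible(x)
}
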