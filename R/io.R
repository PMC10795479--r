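#' Read a mortality schedule from a delimited text file
#'
#' Expects a comma-delimited file with a header row and columns
#' `age_start`, `n` (empty or `"+"` marks the open-ended final group),
#' and either `deaths` and `exposure` or `rate` (optionally with
#' `rate_se`); an `ax` column is optional and missing values are filled
#' by the default rule (see [default_ax()]).
#'
#' @param path file path.
#' @param sep field separator (comma by default).
#' @return a validated [mortality_schedule()].
#' @examples
#' p <- system.file("extdata", "pacific_women_1990.csv",
#'                  package = "lexpdecomp")
#' read_schedule(p)
#' @export
read_schedule <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (!"age_start" %in% names(df))
    stop("missing required column 'age_start' in ", path)
  if (!(("deaths" %in% names(df) && "exposure" %in% names(df)) ||
        "rate" %in% names(df)))
    stop("need either columns deaths + exposure, or rate, in ", path)
  starts <- suppressWarnings(as.numeric(df$age_start))
  if (anyNA(starts))
    stop("non-numeric age_start at row(s): ",
         paste(which(is.na(starts)), collapse = ", "))
  K <- length(starts)
  widths <- NULL
  if ("n" %in% names(df)) {
    nn <- as.character(df$n)
    open_mark <- is.na(nn) | nn == "" | nn == "+" | nn == "Inf"
    widths <- suppressWarnings(as.numeric(nn))
    widths[open_mark] <- Inf
    if (any(is.infinite(widths[-K])))
      stop("only the last age group may be open-ended")
  }
  grid <- tryCatch(age_grid(starts, widths = widths, open = TRUE),
                   error = function(e)
                     stop("invalid age grid in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  getcol <- function(nm) if (nm %in% names(df)) as.numeric(df[[nm]]) else NULL
  tryCatch(
    mortality_schedule(grid,
                       deaths = getcol("deaths"),
                       exposure = getcol("exposure"),
                       rate = getcol("rate"),
                       ax = getcol("ax"),
                       rate_se = getcol("rate_se")),
    error = function(e) stop("invalid schedule in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Write a result table to CSV or JSON
#'
#' Writes life tables, decompositions, schedules and uncertainty results
#' as delimited text (or JSON) at full floating-point precision, with
#' stable column names, so that files round-trip losslessly.
#'
#' Column schemas: mortality schedules use `age_start, n, deaths,
#' exposure, rate, ax, rate_se` (readable by [read_schedule()]); life
#' tables use `age, n, m, a, q, l, L, T, e`; decompositions use `age, n,
#' contribution` (plus one column per cause for cause splits);
#' uncertainty results are written as JSON carrying the method,
#' replicate count, seed, and per-quantity estimate/se/interval.
#'
#' @param x the object to write.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; uncertainty results default to
#'   JSON, everything else to CSV.
#' @param ... unused.
#' @return `invisible(path)`.
#' @export
write_table <- function(x, path, format, ...) UseMethod("write_table")

write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- ""
    out[is.infinite(v)] <- "Inf"
    trimws(out)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.mortality_schedule <- function(x, path, format = c("csv", "json"),
                                           ...) {
  format <- match.arg(format)
  df <- data.frame(age_start = x$age,
                   n = ifelse(is.infinite(x$n), "+", x$n),
                   deaths = x$deaths, exposure = x$exposure,
                   rate = x$rate, ax = x$ax, rate_se = x$rate_se)
  if (format == "csv") write_csv_full(df, path) else json_write(df, path)
}

#' @rdname write_table
#' @export
write_table.life_table <- function(x, path, format = c("csv", "json"), ...) {
  format <- match.arg(format)
  df <- as.data.frame(x)[c("age", "n", "m", "a", "q", "l", "L", "T", "e")]
  if (format == "csv") write_csv_full(df, path) else json_write(df, path)
}

#' @rdname write_table
#' @export
write_table.arriaga_decomposition <- function(x, path,
                                              format = c("csv", "json"), ...) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") write_csv_full(df, path) else json_write(df, path)
}

#' @rdname write_table
#' @export
write_table.cause_decomposition <- function(x, path,
                                            format = c("csv", "json"), ...) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") write_csv_full(df, path) else json_write(df, path)
}

#' @rdname write_table
#' @export
write_table.decomp_uncertainty <- function(x, path,
                                           format = c("json", "csv"), ...) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(method = x$method, reps = x$reps, seed = x$seed,
                    ci_level = x$ci_level, failures = x$failures,
                    truncated = x$truncated,
                    results = data.frame(quantity = x$labels,
                                         estimate = x$estimate, se = x$se,
                                         lower = x$lower, upper = x$upper))
    json_write(payload, path)
  } else {
    write_csv_full(data.frame(quantity = x$labels, estimate = x$estimate,
                              se = x$se, lower = x$lower, upper = x$upper),
                   path)
  }
}

#' @rdname write_table
#' @export
write_table.arriaga <- function(x, path, format = c("csv", "json"), ...) {
  format <- match.arg(format)
  df <- x$decomposition
  df <- rbind(df, c(NA, NA, x$total,
                    if (ncol(df) > 3)
                      utils::tail(x$uncertainty$se, 1)))
  if (format == "csv") write_csv_full(df, path) else json_write(df, path)
}

#' Bundled example schedules: urban Pacific U.S. women, 1990 and 2019
#'
#' Loads the worked-example mortality schedules shipped with the
#' package: age-specific death rates `nmx` and `nax` values for women in
#' the urban Pacific region of the United States, estimated from a 50%
#' sample of vital statistics data, on the standard 0, 1--4, ..., 85+
#' grid.
#'
#' The published source provides rates only. For methods that need death
#' and exposure counts (`counts = TRUE`), the rates are combined with a
#' bundled *synthetic* exposure schedule — a realistic urban-region
#' female age structure at 50%-sample scale, about 6 million
#' person-years — and deaths are derived as `round(exposure * rate)`.
#' Counts built this way are suitable for studying the variance engines
#' at realistic sample sizes but are not the original sample counts.
#'
#' @param year `"1990"` or `"2019"`.
#' @param counts attach synthetic-exposure-based death counts?
#' @return a [mortality_schedule()].
#' @export
pacific_women <- function(year = c("1990", "2019"), counts = FALSE) {
  year <- match.arg(as.character(year), c("1990", "2019"))
  p <- system.file("extdata", paste0("pacific_women_", year, ".csv"),
                   package = "lexpdecomp", mustWork = TRUE)
  s <- read_schedule(p)
  if (!counts) return(s)
  ep <- system.file("extdata", "synthetic_exposure_50pct.csv",
                    package = "lexpdecomp", mustWork = TRUE)
  expo <- utils::read.csv(ep)$exposure
  deaths <- round(s$rate * expo)
  mortality_schedule(sched_grid(s), deaths = deaths, exposure = expo,
                     ax = s$ax)
}
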