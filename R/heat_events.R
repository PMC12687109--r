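#' Species realised thermal limit
#'
#' The realised thermal limit of a species is the spatial maximum, across its
#' range cells, of the per-cell 99th percentile of daily maximum air
#' temperature over the historical baseline (1950-2005 by default).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the type is exposed for sensitivity checks.
#'
#' @param series_by_cell Named list, one numeric vector of daily maximum
#'   temperatures (degC) per range cell, on a 365-day no-leap calendar
#'   starting 1 January of `start_year`.
#' @param start_year First calendar year of each series.
#' @param baseline_years Years over which the percentile is taken.
#' @param prob Percentile (default 0.99).
#' @param quantile_type `stats::quantile` algorithm type.
#' @return Scalar temperature (degC): the species' thermal limit.
#' @export
thermal_limit <- function(series_by_cell, start_year = 1950L,
                          baseline_years = 1950:2005,
                          prob = 0.99, quantile_type = 7) {
  if (length(series_by_cell) == 0L)
    stop("missing data: no cell series supplied", call. = FALSE)
  idx <- days_in_years(start_year, baseline_years)
  p99 <- vapply(series_by_cell, function(v) {
    if (length(v) < max(idx))
      stop("missing data: a cell series does not cover the baseline years",
           call. = FALSE)
    stats::quantile(v[idx], probs = prob, type = quantile_type, names = FALSE)
  }, numeric(1))
  max(p99)
}

# Day indices (1-based) of a set of calendar years within a 365-day no-leap
# series starting at start_year.
days_in_years <- function(start_year, years) {
  offs <- (years - start_year) * 365L
  if (any(offs < 0)) stop("years precede the series start", call. = FALSE)
  as.vector(outer(1:365, offs, `+`))
}

#' Detect extreme heat events in a daily series
#'
#' An extreme heat event is a maximal run of consecutive days on which the
#' daily maximum temperature strictly exceeds the species' thermal limit, for
#' more than five consecutive days: runs of length >= `min_run` (default 6)
#' qualify; a five-day run does not.
#'
#' @param values Numeric vector of daily maximum temperatures (degC).
#' @param t_star Thermal limit (degC).
#' @param min_run Minimum qualifying run length in days (default 6).
#' @return Tibble with one row per event: `start` (day index), `length`
#'   (days) and `max_exceedance` (degC above `t_star`).
#' @export
#' @examples
#' x <- c(rep(20, 10), rep(31, 7), rep(20, 10))
#' detect_events(x, 30)  # one 7-day event, max exceedance 1
detect_events <- function(values, t_star, min_run = 6L) {
  if (min_run < 1) stop("min_run must be >= 1", call. = FALSE)
  exceed <- values > t_star
  if (!any(exceed))
    return(tibble::tibble(start = integer(), length = integer(),
                          max_exceedance = numeric()))
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  starts <- starts[keep]
  lens <- r$lengths[keep]
  tibble::tibble(
    start = starts,
    length = lens,
    max_exceedance = vapply(seq_along(starts), function(i) {
      max(values[starts[i]:(starts[i] + lens[i] - 1L)]) - t_star
    }, numeric(1))
  )
}

#' Summarise the events of one cell-year
#'
#' Frequency is the number of qualifying events; duration the length of the
#' longest event (or, with `duration_rule = "total"`, the total number of
#' event days); intensity the maximum exceedance over event days (or the
#' mean of the per-event maxima with `intensity_rule = "mean"`). All three
#' are zero when no event occurred.
#'
#' @param events Tibble from [detect_events()] for one cell and year.
#' @param duration_rule `"longest"` (default) or `"total"`.
#' @param intensity_rule `"max"` (default) or `"mean"`.
#' @return Named numeric vector `c(frequency, duration, intensity)`.
#' @export
event_metrics <- function(events, duration_rule = c("longest", "total"),
                          intensity_rule = c("max", "mean")) {
  duration_rule <- match.arg(duration_rule)
  intensity_rule <- match.arg(intensity_rule)
  if (nrow(events) == 0L)
    return(c(frequency = 0, duration = 0, intensity = 0))
  c(frequency = nrow(events),
    duration = if (duration_rule == "longest") max(events$length)
               else sum(events$length),
    intensity = if (intensity_rule == "max") max(events$max_exceedance)
                else mean(events$max_exceedance))
}

#' Per-year event metrics of a multi-year daily series
#'
#' Splits a 365-day-calendar series into calendar years and computes
#' frequency, duration and intensity per year. Runs crossing 31 December are
#' split at the year boundary, since the metrics are defined per cell-year.
#'
#' @inheritParams detect_events
#' @inheritParams event_metrics
#' @param start_year Calendar year of day 1.
#' @return Tibble with columns `year`, `frequency`, `duration`, `intensity`.
#' @export
yearly_event_metrics <- function(values, t_star, start_year = 1950L,
                                 min_run = 6L,
                                 duration_rule = c("longest", "total"),
                                 intensity_rule = c("max", "mean")) {
  duration_rule <- match.arg(duration_rule)
  intensity_rule <- match.arg(intensity_rule)
  out <- year_metrics_core(values, t_star, min_run, duration_rule,
                           intensity_rule)
  tibble::tibble(year = start_year + seq_len(nrow(out)) - 1L,
                 frequency = out[, 1], duration = out[, 2],
                 intensity = out[, 3])
}

# Vectorised core of yearly_event_metrics: one pass over the whole series,
# runs cut both at exceedance changes and at calendar-year boundaries, then
# per-run maxima gathered only for the (few) qualifying runs. Returns a
# matrix n_years x 3 (frequency, duration, intensity).
year_metrics_core <- function(values, t_star, min_run = 6L,
                              duration_rule = "longest",
                              intensity_rule = "max") {
  n <- length(values)
  n_years <- n %/% 365L
  if (n_years * 365L != n)
    stop("series length must be a multiple of 365 days", call. = FALSE)
  out <- matrix(0, n_years, 3L,
                dimnames = list(NULL, c("frequency", "duration", "intensity")))
  exceed <- values > t_star
  if (!any(exceed)) return(out)
  year_of <- rep.int(seq_len(n_years), rep.int(365L, n_years))
  newrun <- c(TRUE, exceed[-1L] != exceed[-n] | year_of[-1L] != year_of[-n])
  run_id <- cumsum(newrun)
  lens <- tabulate(run_id)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  qual <- which(exceed[starts] & lens >= min_run)
  if (length(qual) == 0L) return(out)
  dx <- values - t_star
  for (k in qual) {
    y <- year_of[starts[k]]
    out[y, 1L] <- out[y, 1L] + 1
    out[y, 2L] <- if (duration_rule == "longest") max(out[y, 2L], lens[k])
                  else out[y, 2L] + lens[k]
    ex <- max(dx[starts[k]:ends[k]])
    # for the mean rule accumulate the sum here; divide by frequency below
    out[y, 3L] <- if (intensity_rule == "max") max(out[y, 3L], ex)
                  else out[y, 3L] + ex
  }
  if (intensity_rule == "mean") {
    has <- out[, 1L] > 0
    out[has, 3L] <- out[has, 3L] / out[has, 1L]
  }
  out
}

#' Baseline maxima of the event metrics
#'
#' The species-wide maximum of each event metric over all range cells and
#' baseline years; the yardstick against which future events are judged.
#'
#' @param metrics Tibble with columns `frequency`, `duration`, `intensity`
#'   covering the species' range cells x baseline years.
#' @return Named numeric vector `c(max_frequency, max_duration, max_intensity)`.
#' @export
baseline_maxima <- function(metrics) {
  if (nrow(metrics) == 0L)
    return(c(max_frequency = 0, max_duration = 0, max_intensity = 0))
  c(max_frequency = max(metrics$frequency),
    max_duration = max(metrics$duration),
    max_intensity = max(metrics$intensity))
}

#' Climate suitability of cell-years against the baseline maxima
#'
#' A cell-year is climatically unsuitable when any one of its event metrics
#' strictly exceeds the species' historical maximum — higher frequency,
#' longer duration or greater intensity. Equality with the maximum remains
#' suitable.
#'
#' @param metrics Tibble with columns `frequency`, `duration`, `intensity`
#'   (one or more cell-years).
#' @param baseline Named vector from [baseline_maxima()].
#' @return Logical vector, `TRUE` = suitable.
#' @export
climate_suitable <- function(metrics, baseline) {
  !(metrics$frequency > baseline[["max_frequency"]] |
      metrics$duration > baseline[["max_duration"]] |
      metrics$intensity > baseline[["max_intensity"]])
}

#' Combine per-model suitability flags across the climate ensemble
#'
#' The ensemble verdict is the median of the binary per-model flags: a
#' cell-year is unsuitable when a strict majority of models flag it
#' unsuitable (3 of 5 for a five-model ensemble). Requires an odd number of
#' models, otherwise the median of a binary set is ambiguous.
#'
#' @param suitable Logical vector, one flag per model (`TRUE` = suitable).
#' @param rule Combination rule; only `"median"` is defined.
#' @return Scalar logical: the ensemble flag.
#' @export
combine_gcms <- function(suitable, rule = "median") {
  if (!identical(rule, "median"))
    stop("unknown combination rule: ", rule, call. = FALSE)
  n <- length(suitable)
  if (n %% 2L == 0L)
    stop("invalid config: the median rule needs an odd number of models",
         call. = FALSE)
  sum(!suitable) < (n + 1L) / 2L
}
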