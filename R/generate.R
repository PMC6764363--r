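#' Parameters of the synthetic flowering-population generator
#'
#' The generator emulates a prairie-forb population of the *Echinacea
#' angustifolia* kind: each plant flowers once per season over a contiguous
#' window of days.  Per-plant onset is a year-level normal shift plus a
#' right-skewed gamma draw, so that the population's daily flower-count curve
#' rises quickly, peaks, and declines gradually; flowering duration is an
#' independent truncated-normal draw.
#'
#' @param n_plants Number of plants (default 286).
#' @param n_years Number of years (default 11).
#' @param first_year Calendar label of the first year (default 1995).
#' @param onset_location Earliest possible mean onset, DOY (default 175).
#' @param onset_skew Gamma shape of the per-plant onset delay (default 6);
#'   smaller values give stronger right skew.
#' @param onset_scale Gamma scale of the onset delay, days (default 2).
#' @param duration_mean Mean flowering duration, days (default 25).
#' @param duration_sd SD of flowering duration, days (default 4).
#' @param duration_min Minimum duration, days (default 1).
#' @param year_effect_sd SD of the additive normal year effect on onset,
#'   days (default 5).
#' @param seed Integer seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_plants = 286L, n_years = 11L, first_year = 1995L,
                             onset_location = 175, onset_skew = 6,
                             onset_scale = 2, duration_mean = 25,
                             duration_sd = 4, duration_min = 1L,
                             year_effect_sd = 5, seed = 1L) {
  p <- list(n_plants = as.integer(n_plants), n_years = as.integer(n_years),
            first_year = as.integer(first_year),
            onset_location = onset_location, onset_skew = onset_skew,
            onset_scale = onset_scale, duration_mean = duration_mean,
            duration_sd = duration_sd, duration_min = as.integer(duration_min),
            year_effect_sd = year_effect_sd, seed = as.integer(seed))
  if (p$n_plants < 1L || p$n_years < 1L) stop("need n_plants >= 1 and n_years >= 1")
  if (p$duration_mean <= 0) stop("duration_mean must be positive")
  if (p$onset_skew <= 0 || p$onset_scale <= 0) stop("onset shape/scale must be positive")
  if (p$onset_location < 1) stop("onset_location must be >= 1")
  # a-priori overflow check: the mean flowering window must fit in the year
  if (p$onset_location + p$onset_skew * p$onset_scale + p$duration_mean - 1 > 365)
    stop("parameters imply flowering windows beyond DOY 365")
  class(p) <- c("generator_params", class(p))
  p
}

#' Generate ground-truth flowering schedules
#'
#' Draws one flowering window per plant per year.  Onset is
#' `onset_location + year effect + Gamma(onset_skew, onset_scale)`, rounded
#' to an integer DOY; duration is `Normal(duration_mean, duration_sd)`
#' truncated below at `duration_min`; windows are truncated so that
#' `end_doy <= 365`.  Within its window a plant is continuously in flower.
#'
#' @param params A [generator_params()] list (or arguments passed on to it
#'   via `...`).
#' @param ... Used to build `params` when `params` is missing.
#' @return A schedule data frame (see [read_schedules()]), `n_plants *
#'   n_years` rows.  The same seed always yields the identical table.
#' @examples
#' sched <- generate_schedules(generator_params(n_plants = 20, n_years = 2))
#' head(sched)
#' @export
generate_schedules <- function(params, ...) {
  if (missing(params)) params <- generator_params(...)
  if (!inherits(params, "generator_params")) params <- do.call(generator_params, params)
  set.seed(params$seed)
  years <- params$first_year + seq_len(params$n_years) - 1L
  ids <- sprintf("p%03d", seq_len(params$n_plants))
  out <- vector("list", params$n_years)
  for (i in seq_len(params$n_years)) {
    year_shift <- rnorm(1L, 0, params$year_effect_sd)
    onset <- params$onset_location + year_shift +
      rgamma(params$n_plants, shape = params$onset_skew, scale = params$onset_scale)
    start <- pmin(365L, pmax(1L, as.integer(round(onset))))
    dur <- pmax(params$duration_min,
                as.integer(round(rnorm(params$n_plants, params$duration_mean,
                                       params$duration_sd))))
    end <- pmin(365L, start + dur - 1L)
    out[[i]] <- data.frame(plant_id = ids, year = years[i],
                           start_doy = start, end_doy = end,
                           stringsAsFactors = FALSE)
  }
  validate_schedules(do.call(rbind, out))
}

#' Keep only plants flowering for more than `min_days` days
#'
#' The individual-scale analysis uses only plant-years whose flowering
#' window is strictly longer than `min_days` (default 20), so that even the
#' smallest sample-size/presence-fraction scenario has enough flowering days
#' to draw from.
#'
#' @param schedules A schedule data frame.
#' @param min_days Strict lower bound on window length in days (default 20):
#'   a window of exactly `min_days` days is dropped.
#' @return The filtered schedule data frame.
#' @export
filter_long_flowering <- function(schedules, min_days = 20L) {
  if (min_days < 1L) stop("min_days must be >= 1")
  keep <- (schedules$end_doy - schedules$start_doy + 1L) > min_days
  schedules[keep, , drop = FALSE]
}
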