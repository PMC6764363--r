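#' Number of presence records in a sample
#'
#' `n_obs * presence_fraction` rounded half away from zero, with a floor of
#' one presence, so every scenario of the grid is well defined (e.g. 5
#' observations at 25% presence gives `round(1.25) = 1`).
#'
#' @param n_obs Total sample size.
#' @param presence_fraction Fraction of presence records, in (0, 1).
#' @return Integer number of presence records.
#' @export
presence_count <- function(n_obs, presence_fraction) {
  max(1L, as.integer(floor(n_obs * presence_fraction + 0.5)))
}

#' Draw a randomized status sample
#'
#' Draws a sample of exactly `n_obs` status observations containing exactly
#' [presence_count()] presences, uniformly without replacement from the
#' presence and absence pools of plant-days.  `draw_population_sample()`
#' pools all plants of a year; `draw_individual_sample()` uses the 365 days
#' of a single plant.  Absences come from the full calendar year, including
#' pre- and post-season days.
#'
#' @param daily Logical plant-by-DOY status matrix from
#'   [expand_daily_status()].
#' @param n_obs Total sample size.
#' @param presence_fraction Fraction of presence records, in (0, 1).
#' @return An observation data frame (see [read_observations()]).  An error
#'   naming the exhausted pool is raised when a pool is smaller than the
#'   number of records requested from it.
#' @examples
#' sched <- generate_schedules(generator_params(n_plants = 30, n_years = 1))
#' daily <- expand_daily_status(sched, 1995)
#' set.seed(1)
#' samp <- draw_population_sample(daily, n_obs = 10, presence_fraction = 0.5)
#' table(samp$status)
#' @export
draw_population_sample <- function(daily, n_obs, presence_fraction) {
  pres_cells <- which(daily)
  abs_cells <- which(!daily)
  n_pres <- presence_count(n_obs, presence_fraction)
  cells <- draw_cells(pres_cells, abs_cells, n_pres, n_obs - n_pres)
  np <- nrow(daily)
  data.frame(
    plant_id = rownames(daily)[(cells$idx - 1L) %% np + 1L],
    year = attr(daily, "year") %||% NA_integer_,
    doy = (cells$idx - 1L) %/% np + 1L,
    status = cells$status,
    stringsAsFactors = FALSE)
}

#' @rdname draw_population_sample
#' @param status Logical status vector over DOY 1-365 for one plant (a row
#'   of the matrix from [expand_daily_status()]).
#' @param plant_id Identifier attached to the drawn records.
#' @param year Year attached to the drawn records.
#' @export
draw_individual_sample <- function(status, plant_id, n_obs, presence_fraction,
                                   year = NA_integer_) {
  stopifnot(length(status) == 365L)
  n_pres <- presence_count(n_obs, presence_fraction)
  cells <- draw_cells(which(status), which(!status), n_pres, n_obs - n_pres)
  data.frame(plant_id = plant_id, year = year, doy = cells$idx,
             status = cells$status, stringsAsFactors = FALSE)
}

# core draw: uniform, without replacement, exact composition
draw_cells <- function(pres_pool, abs_pool, n_pres, n_abs) {
  if (length(pres_pool) < n_pres)
    stop("presence pool exhausted: ", length(pres_pool),
         " flowering plant-days available, ", n_pres, " requested")
  if (length(abs_pool) < n_abs)
    stop("absence pool exhausted: ", length(abs_pool),
         " non-flowering plant-days available, ", n_abs, " requested")
  idx <- c(pres_pool[sample.int(length(pres_pool), n_pres)],
           abs_pool[sample.int(length(abs_pool), n_abs)])
  list(idx = idx, status = rep(c("present", "absent"), c(n_pres, n_abs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
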