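#' Expand schedules to daily presence/absence status
#'
#' Builds the full status table the sampling routines draw from: for every
#' plant and every DOY 1-365 of one year, whether the plant was in flower
#' (`start_doy <= doy <= end_doy`).  Plants present in `schedules` but with
#' no window in the given year get an all-absent row.
#'
#' @param schedules A schedule data frame.
#' @param year The year to expand.
#' @return A logical matrix, plants in rows (rownames = plant ids, all
#'   plants appearing anywhere in `schedules`), DOY 1-365 in columns;
#'   `TRUE` = flowering present.  The year is stored in `attr(, "year")`.
#' @export
expand_daily_status <- function(schedules, year) {
  ids <- sort(unique(schedules$plant_id))
  m <- matrix(FALSE, nrow = length(ids), ncol = 365L,
              dimnames = list(ids, NULL))
  sy <- schedules[schedules$year == year, , drop = FALSE]
  for (i in seq_len(nrow(sy)))
    m[sy$plant_id[i], sy$start_doy[i]:sy$end_doy[i]] <- TRUE
  attr(m, "year") <- year
  m
}

#' True transition dates of one year
#'
#' Computes the ground-truth metrics the estimators are judged against:
#' population onset is the DOY of the first observed flower, peak the DOY
#' when the most flowers were open (ties broken to the earliest such day),
#' and end the last DOY a flower was observed; individual onset/end are each
#' plant's window bounds.
#'
#' @param schedules A schedule data frame.
#' @param year The year to evaluate.
#' @return A list with `year`, `population` (named vector `onset`, `peak`,
#'   `end`), and `individual` (data frame `plant_id`, `onset`, `end`).
#' @export
compute_true_metrics <- function(schedules, year) {
  sy <- schedules[schedules$year == year, , drop = FALSE]
  if (nrow(sy) == 0L) stop("no flowering in year ", year)
  count <- daily_count(sy)
  list(year = year,
       population = c(onset = min(sy$start_doy),
                      peak = which.max(count),  # earliest maximal DOY
                      end = max(sy$end_doy)),
       individual = data.frame(plant_id = sy$plant_id,
                               onset = sy$start_doy, end = sy$end_doy,
                               stringsAsFactors = FALSE))
}

# number of plants in flower on each DOY 1-365
daily_count <- function(schedules) {
  tabulate(unlist(Map(seq.int, schedules$start_doy, schedules$end_doy)), 365L)
}

#' True metric tables for all years
#'
#' @param schedules A schedule data frame.
#' @return A list of two data frames: `population` (`year`, `onset`, `peak`,
#'   `end`) and `individual` (`plant_id`, `year`, `onset`, `end`).
#' @export
true_metrics_table <- function(schedules) {
  years <- sort(unique(schedules$year))
  pop <- do.call(rbind, lapply(years, function(y) {
    tm <- compute_true_metrics(schedules, y)
    data.frame(year = y, onset = tm$population[["onset"]],
               peak = tm$population[["peak"]], end = tm$population[["end"]])
  }))
  ind <- schedules[c("plant_id", "year")]
  ind$onset <- schedules$start_doy
  ind$end <- schedules$end_doy
  list(population = pop, individual = ind)
}
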