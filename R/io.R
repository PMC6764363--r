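#' Read a flowering-schedule table
#'
#' A flowering schedule gives the ground-truth first and last day of flowering
#' (start and end of pollen production) for one plant in one year.  The CSV
#' must have header columns `plant_id`, `year`, `start_doy`, `end_doy`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `plant_id` (character), `year` (integer),
#'   `start_doy`, `end_doy` (integer DOY, 1-365), one row per plant-year.
#' @details Rows violating `1 <= start_doy <= end_doy <= 365`, or duplicated
#'   `(plant_id, year)` pairs, raise an error naming the offending line.
#' @seealso [write_schedules()], [read_observations()]
#' @export
read_schedules <- function(path) {
  df <- read.csv(path, colClasses = c(plant_id = "character"))
  need <- c("plant_id", "year", "start_doy", "end_doy")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  validate_schedules(df)
}

#' @rdname read_schedules
#' @param schedules A schedule data frame as returned by [read_schedules()]
#'   or [generate_schedules()].
#' @export
write_schedules <- function(schedules, path) {
  schedules <- validate_schedules(schedules)
  write.csv(schedules, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_schedules
#' @export
validate_schedules <- function(schedules) {
  df <- as.data.frame(schedules)
  df$plant_id <- as.character(df$plant_id)
  for (col in c("year", "start_doy", "end_doy")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v != as.integer(v)))
      stop("non-integer or missing '", col, "' at line ",
           bad_line(is.na(v) | v != round(v)))
    df[[col]] <- as.integer(v)
  }
  bad <- df$start_doy < 1L | df$end_doy > 365L | df$start_doy > df$end_doy
  if (any(bad))
    stop("invalid flowering window (need 1 <= start_doy <= end_doy <= 365) ",
         "at line ", bad_line(bad))
  dup <- duplicated(df[c("plant_id", "year")])
  if (any(dup))
    stop("duplicate (plant_id, year) at line ", bad_line(dup))
  df
}

# line number in the source CSV (header = line 1)
bad_line <- function(bad) which(bad)[1L] + 1L

#' Read a status-observation table
#'
#' A status observation records whether flowering was present or absent for
#' one plant on one day.  The CSV must have header columns `plant_id`,
#' `year`, `doy`, `status`; `status` may be spelled `present`/`absent`
#' (case-insensitive) or `1`/`0`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `plant_id` (character), `year`, `doy`
#'   (integer, 1-365), and `status` (character, `"present"` or `"absent"`).
#' @seealso [write_observations()], [read_schedules()]
#' @export
read_observations <- function(path) {
  df <- read.csv(path, colClasses = c(plant_id = "character", status = "character"))
  need <- c("plant_id", "year", "doy", "status")
  if (!all(need %in% names(df)))
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  validate_observations(df[need])
}

#' @rdname read_observations
#' @param observations An observation data frame.
#' @export
write_observations <- function(observations, path) {
  observations <- validate_observations(observations)
  write.csv(observations, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_observations
#' @export
validate_observations <- function(observations) {
  df <- as.data.frame(observations)
  df$plant_id <- as.character(df$plant_id)
  for (col in c("year", "doy")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v != as.integer(v)))
      stop("non-integer or missing '", col, "' at line ",
           bad_line(is.na(v) | v != round(v)))
    df[[col]] <- as.integer(v)
  }
  if (any(df$doy < 1L | df$doy > 365L))
    stop("doy outside 1-365 at line ", bad_line(df$doy < 1L | df$doy > 365L))
  tok <- tolower(trimws(as.character(df$status)))
  status <- ifelse(tok %in% c("present", "1"), "present",
                   ifelse(tok %in% c("absent", "0"), "absent", NA))
  if (anyNA(status))
    stop("unknown status token '", tok[which(is.na(status))[1L]],
         "' at line ", bad_line(is.na(status)),
         " (expected present/absent or 1/0)")
  df$status <- status
  df
}

# split an observation frame into presence / absence DOY vectors
obs_doys <- function(observations) {
  observations <- validate_observations(observations)
  list(presence = observations$doy[observations$status == "present"],
       absence  = observations$doy[observations$status == "absent"],
       plant_id = observations$plant_id)
}
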