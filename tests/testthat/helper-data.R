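# Small builders shared by the tests.

make_obs <- function(presence = integer(), absence = integer(),
                     plant_id = "p1", year = 1995L) {
  data.frame(
    plant_id = plant_id,
    year = year,
    doy = c(presence, absence),
    status = rep(c("present", "absent"), c(length(presence), length(absence))),
    stringsAsFactors = FALSE)
}

make_schedules <- function(plant_id, year, start_doy, end_doy) {
  data.frame(plant_id = plant_id, year = year,
             start_doy = start_doy, end_doy = end_doy,
             stringsAsFactors = FALSE)
}

# full daily census of one plant: every DOY observed once
census_obs <- function(start, end, plant_id = "p1") {
  doys <- 1:365
  make_obs(presence = doys[doys >= start & doys <= end],
           absence = doys[doys < start | doys > end],
           plant_id = plant_id)
}

# the default synthetic population, generated once per test run
default_schedules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_schedules(generator_params())
    cache
  }
})
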