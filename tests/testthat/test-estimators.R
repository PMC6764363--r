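test_that("first/last observed are the extreme presence dates", {
  obs <- make_obs(presence = c(200, 195, 210), absence = c(100, 300))
  expect_equal(first_observed(obs), 195)
  expect_equal(last_observed(obs), 210)
  expect_equal(first_observed(make_obs(presence = 187)), 187)
  expect_true(is.na(first_observed(make_obs(absence = c(150, 250)))))
  expect_true(is.na(last_observed(make_obs(absence = 150))))
})

test_that("mean first observed matches the closed-form discrete-uniform minimum", {
  set.seed(1234)
  mins <- replicate(1000, first_observed(
    make_obs(presence = sample(180:209, 10, replace = TRUE))))
  expected <- oracle_discrete_uniform_emin(180, 209, 10)
  expect_lt(abs(mean(mins) - expected), 0.35)  # ~4 SE of the Monte Carlo mean
})

test_that("midway estimators take midpoints and respect the 7-day gap rule", {
  expect_equal(midway_onset(make_obs(presence = c(186, 190), absence = 180)), 183)
  expect_equal(midway_onset(make_obs(presence = 186, absence = 181)), 183.5)
  expect_true(is.na(midway_onset(make_obs(presence = 186, absence = 178),
                                 max_gap = 7)))  # gap 8
  expect_equal(midway_onset(make_obs(presence = 186, absence = 179), max_gap = 7),
               182.5)  # gap exactly 7 is allowed
  expect_true(is.na(midway_onset(make_obs(presence = 186))))          # no absence
  expect_true(is.na(midway_onset(make_obs(absence = c(150, 180)))))   # no presence

  expect_equal(midway_end(make_obs(presence = c(190, 200), absence = 206)), 203)
  expect_true(is.na(midway_end(make_obs(presence = 200, absence = 210),
                               max_gap = 7)))  # gap 10
  expect_true(is.na(midway_end(make_obs(presence = c(190, 200)))))
  # absences before the last presence do not anchor the end estimate
  expect_true(is.na(midway_end(make_obs(presence = c(190, 200), absence = 195))))
})

test_that("midway output lies strictly between its anchors", {
  set.seed(77)
  for (i in 1:50) {
    a <- sample(150:200, 1); fp <- a + sample(1:10, 1)
    est <- midway_onset(make_obs(presence = c(fp, fp + 5), absence = a))
    expect_true(est > a && est < fp)
  }
})

test_that("a full daily census pins midway onset to half a day", {
  obs <- census_obs(183, 210)
  expect_equal(midway_onset(obs), 182.5)
  expect_equal(midway_end(obs), 210.5)
  expect_lte(abs(midway_onset(obs) - 183), 0.5)
})

test_that("mean midway averages usable plants only", {
  obs <- rbind(
    make_obs(presence = c(186, 190), absence = 180, plant_id = "p1"),  # 183
    make_obs(presence = 190, absence = 184, plant_id = "p2"))          # 187
  expect_equal(mean_midway(obs, which = "onset"), 185)
  # only one qualifying plant under the 7-day rule -> that plant's value
  obs2 <- rbind(
    make_obs(presence = 186, absence = 181, plant_id = "p1"),  # gap 5 -> 183.5
    make_obs(presence = 200, absence = 150, plant_id = "p2"))  # gap 50
  expect_equal(mean_midway(obs2, max_gap = 7, which = "onset"), 183.5)
  # no plant with a prior absence -> unusable
  obs3 <- rbind(make_obs(presence = 186, plant_id = "p1"),
                make_obs(presence = 200, absence = 250, plant_id = "p2"))
  expect_true(is.na(mean_midway(obs3, which = "onset")))
})

test_that("the Weibull endpoint matches the transcribed weight equations", {
  x <- c(150, 152, 155, 159, 163)
  # frozen value from the independent transcription, evaluated once
  expect_equal(weibull_endpoint(x, "earliest"), 146.1847565714, tolerance = 1e-9)
  expect_equal(weibull_endpoint(x, "latest"), 170.9153771156, tolerance = 1e-9)
  expect_equal(weibull_endpoint(x, "earliest"), oracle_ole_lower(x))
  expect_equal(weibull_endpoint(x, "latest"), oracle_ole_upper(x))
  set.seed(42)
  for (i in 1:30) {
    y <- sort(sample(100:300, sample(4:25, 1)))
    expect_equal(weibull_endpoint(y, "earliest"), oracle_ole_lower(y),
                 tolerance = 1e-9)
    expect_equal(weibull_endpoint(y, "latest"), oracle_ole_upper(y),
                 tolerance = 1e-9)
  }
})

test_that("the Weibull endpoint extrapolates beyond the sample extremes", {
  set.seed(9)
  for (i in 1:40) {
    y <- runif(sample(4:30, 1), 150, 250)
    expect_lte(weibull_endpoint(y, "earliest"), min(y) + 1e-9)
    expect_gte(weibull_endpoint(y, "latest"), max(y) - 1e-9)
  }
})

test_that("degenerate Weibull inputs fall back or are unusable", {
  expect_equal(weibull_endpoint(rep(187, 5), "earliest"), 187)  # zero spread
  expect_true(is.na(weibull_endpoint(c(150, 152, 155), "earliest")))  # < 4 distinct
  expect_true(is.na(weibull_endpoint(c(150, 150, 152, 155), "latest")))
  expect_true(is.na(weibull_endpoint(numeric(0), "earliest")))
})

test_that("logistic transitions recover a known flowering curve", {
  set.seed(501)
  doy <- sample(150:250, 200, replace = TRUE)
  status <- rbinom(200, 1, plogis((doy - 200) / 5))
  obs <- make_obs(presence = doy[status == 1], absence = doy[status == 0])
  est <- logistic_transition(obs, 0.5, "onset")
  expect_lte(abs(est - 200), 2)
  # monotone curve: crossings ordered in the threshold
  e05 <- logistic_transition(obs, 0.05, "onset")
  e95 <- logistic_transition(obs, 0.95, "onset")
  expect_lte(e05, e95)
})

test_that("perfectly separated data yield a crossing inside the gap", {
  obs <- make_obs(presence = c(200, 205, 210, 215),
                  absence = c(170, 180, 185, 190))
  est <- logistic_transition(obs, 0.5, "onset")
  expect_true(est >= 190 && est <= 200)
})

test_that("single-class data are unusable for the logistic estimator", {
  expect_true(is.na(logistic_transition(make_obs(presence = c(180, 190, 200)),
                                        0.5, "onset")))
  expect_true(is.na(logistic_transition(make_obs(absence = c(180, 190)),
                                        0.5, "onset")))
  # onset pre-filter drops absences after the last presence: single class again
  obs <- make_obs(presence = c(180, 190), absence = c(250, 260))
  expect_true(is.na(logistic_transition(obs, 0.5, "onset")))
})

test_that("GAM curves are probabilities peaking inside the flowering season", {
  set.seed(902)
  pres <- sample(190:210, 40, replace = TRUE)
  abs <- sample(c(100:185, 215:300), 60, replace = TRUE)
  curve <- gam_fit(make_obs(presence = pres, absence = abs), "peak")
  expect_s3_class(curve, "probability_curve")
  expect_true(all(curve$p >= 0 & curve$p <= 1))
  expect_true(gam_peak(curve) >= 190 && gam_peak(curve) <= 210)
  expect_null(gam_fit(make_obs(presence = pres), "peak"))  # single class
})

test_that("curve transitions follow the threshold rules", {
  p <- rep(0, 365); p[200:210] <- 1
  step <- probability_curve(p)
  expect_equal(gam_transition(step, 0.5, "onset"), 200)
  expect_equal(gam_transition(step, 0.5, "end"), 211)
  expect_equal(gam_peak(step), 200)
  flat <- probability_curve(rep(0.3, 365))
  expect_true(is.na(gam_transition(flat, 0.5, "onset")))
  expect_true(is.na(gam_transition(flat, 0.5, "end")))
  expect_equal(gam_peak(flat), 1)  # documented degenerate: earliest tie
  # ordered crossings for a unimodal curve
  bump <- probability_curve(exp(-((1:365 - 200) / 20)^2))
  expect_lte(gam_transition(bump, 0.05, "onset"),
             gam_transition(bump, 0.95, "onset"))
})

test_that("survival median matches the hand product-limit example", {
  obs <- make_obs(presence = c(170, 180, 190), absence = c(150, 160))
  expect_equal(survival_median(obs), 180)  # S(170)=2/3, S(180)=1/3
  expect_equal(survival_median(make_obs(presence = c(170, 180, 190))), 180)
  # one event among many later censorings: survival never reaches 0.5
  obs2 <- make_obs(presence = 170, absence = c(180, 190, 200, 210))
  expect_true(is.na(survival_median(obs2)))
  expect_true(is.na(survival_median(make_obs(absence = c(150, 160)))))
})

test_that("survival median equals the brute-force product limit on random sets", {
  set.seed(61)
  for (i in 1:200) {
    n_ev <- sample(1:10, 1); n_cs <- sample(0:10, 1)
    ev <- sample(150:250, n_ev, replace = TRUE)
    cs <- if (n_cs) sample(150:250, n_cs, replace = TRUE) else integer(0)
    got <- survival_median(make_obs(presence = ev, absence = cs))
    expect_identical(is.na(got), is.na(oracle_km_median(ev, cs)))
    if (!is.na(got)) expect_equal(got, oracle_km_median(ev, cs))
  }
})

test_that("mean flowering averages presences and ignores order", {
  expect_equal(mean_flowering(c(180, 182, 187)), 183)
  expect_equal(mean_flowering(187), 187)
  expect_equal(mean_flowering(c(187, 182, 180)), mean_flowering(c(180, 182, 187)))
  expect_true(is.na(mean_flowering(numeric(0))))
  # symmetric presence set -> its centre
  expect_equal(mean_flowering(c(190, 195, 200, 205, 210)), 200)
})

test_that("the dispatcher routes estimators and flags usability", {
  obs <- make_obs(presence = c(186, 190, 195, 201), absence = c(180, 210))
  est <- estimate_transition(obs, "midway", "onset")
  expect_s3_class(est, "phenodate_estimate")
  expect_equal(est$estimate, 183)
  expect_true(est$usable)
  expect_output(print(est), "midway of flowering onset")

  bad <- estimate_transition(make_obs(absence = 150), "first_observed", "onset")
  expect_false(bad$usable)
  expect_true(is.na(bad$estimate))

  expect_error(estimate_transition(obs, "first_observed", "end"), "onset only")
  expect_error(estimate_transition(obs, "nope", "onset"), "unknown estimator")
  expect_equal(estimate_transition(obs, "weibull", "onset")$estimate,
               weibull_endpoint(c(186, 190, 195, 201), "earliest"))
})
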