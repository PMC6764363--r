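#' First / last observed flowering date
#'
#' The simplest estimators: the earliest presence DOY estimates onset, the
#' latest presence DOY estimates end.  Only presence observations are used.
#'
#' @param obs An observation data frame (see [read_observations()]).
#' @return Estimated DOY, or `NA` when no presence observation exists
#'   (the estimate is then "unusable").
#' @export
first_observed <- function(obs) {
  d <- obs_doys(obs)
  if (length(d$presence) == 0L) return(NA_real_)
  as.numeric(min(d$presence))
}

#' @rdname first_observed
#' @export
last_observed <- function(obs) {
  d <- obs_doys(obs)
  if (length(d$presence) == 0L) return(NA_real_)
  as.numeric(max(d$presence))
}

#' Midway transition estimators for a single plant
#'
#' `midway_onset()` is the midpoint between the first observed presence and
#' the latest absence before it; `midway_end()` mirrors this at the end of
#' the season (midpoint of the last presence and the earliest absence after
#' it).  With `max_gap = 7` ("7-day" variants) the anchoring absence must lie
#' within 7 days of the presence, otherwise the estimate is unusable.
#'
#' @param obs Observations of a single plant-year.
#' @param max_gap Maximum days between the anchoring absence and presence,
#'   or `NULL` for no restriction.
#' @return Estimated DOY (possibly fractional), or `NA` when no presence
#'   exists, no anchoring absence exists, or the gap exceeds `max_gap`.
#' @export
midway_onset <- function(obs, max_gap = NULL) {
  d <- obs_doys(obs)
  mid_onset(d$presence, d$absence, max_gap)
}

#' @rdname midway_onset
#' @export
midway_end <- function(obs, max_gap = NULL) {
  d <- obs_doys(obs)
  mid_end(d$presence, d$absence, max_gap)
}

mid_onset <- function(pres, abs, max_gap = NULL) {
  if (length(pres) == 0L) return(NA_real_)
  fp <- min(pres)
  prior <- abs[abs < fp]
  if (length(prior) == 0L) return(NA_real_)
  anchor <- max(prior)
  if (!is.null(max_gap) && fp - anchor > max_gap) return(NA_real_)
  (fp + anchor) / 2
}

mid_end <- function(pres, abs, max_gap = NULL) {
  if (length(pres) == 0L) return(NA_real_)
  lp <- max(pres)
  after <- abs[abs > lp]
  if (length(after) == 0L) return(NA_real_)
  anchor <- min(after)
  if (!is.null(max_gap) && anchor - lp > max_gap) return(NA_real_)
  (lp + anchor) / 2
}

#' Mean midway estimator for a population sample
#'
#' Applies the per-plant midway rule to every plant in a population sample
#' and averages the per-plant estimates over the plants for which the rule
#' is usable.  Unusable when no plant has both a presence and a qualifying
#' anchoring absence.
#'
#' @inheritParams midway_onset
#' @param which `"onset"` or `"end"`.
#' @return Estimated DOY or `NA`.
#' @export
mean_midway <- function(obs, max_gap = NULL, which = c("onset", "end")) {
  which <- match.arg(which)
  obs <- validate_observations(obs)
  per_plant <- split(obs, obs$plant_id)
  vals <- vapply(per_plant, function(o) {
    d <- obs_doys(o)
    if (which == "onset") mid_onset(d$presence, d$absence, max_gap)
    else mid_end(d$presence, d$absence, max_gap)
  }, numeric(1))
  mean_mid(vals)
}

mean_mid <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# mean midway on raw vectors (fast path for the Monte Carlo loops)
mean_mid_vec <- function(pres, abs, pres_plant, abs_plant, max_gap, which) {
  plants <- unique(c(pres_plant, abs_plant))
  vals <- vapply(plants, function(pl) {
    p <- pres[pres_plant == pl]; a <- abs[abs_plant == pl]
    if (which == "onset") mid_onset(p, a, max_gap) else mid_end(p, a, max_gap)
  }, numeric(1))
  mean_mid(vals)
}

#' Weibull-weighted optimal linear endpoint estimator
#'
#' Estimates the date at which flowering began (or ceased) beyond the range
#' of the observed presences, using only presence observations.  The
#' estimate is the weighted sum of the distinct ordered presence dates,
#' `sum(lambda_i * T_(i))`, with weights `lambda = solve(L, e) /
#' sum(solve(L, e))` built from a Weibull-shape estimate of the tail
#' (`L[i, j] = gamma(2v + j') gamma(v + i') / (gamma(v + j') gamma(i'))`
#' with `i' = min(i, j)`, `j' = max(i, j)`, and shape
#' `v = mean over i of log((T_(k) - T_(1)) / (T_(k) - T_(i)))` on the
#' reversed dates) - the optimal-linear-estimation formulation used to date
#' extinctions from sighting records.  The earliest endpoint is computed by
#' negating the dates, estimating the latest endpoint, and negating back;
#' the estimate never lies inside the observed range.
#'
#' @param presence_doys Numeric vector of presence DOYs (a fractional grid
#'   is allowed); duplicated dates are collapsed to distinct values.
#' @param direction `"earliest"` (onset) or `"latest"` (end).
#' @param k_min Minimum number of distinct dates required (default 4);
#'   fewer gives `NA`.  If all dates coincide that common date is returned.
#' @return Estimated DOY or `NA`.
#' @examples
#' weibull_endpoint(c(150, 152, 155, 159, 163), "earliest")
#' @export
weibull_endpoint <- function(presence_doys, direction = c("earliest", "latest"),
                             k_min = 4L) {
  direction <- match.arg(direction)
  x <- unique(as.numeric(presence_doys))
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(unique(x)) == 1L) return(x[1])
  if (length(x) < k_min) return(NA_real_)
  if (direction == "earliest") -ole_latest(-x) else ole_latest(x)
}

# optimal linear estimate of the upper endpoint from distinct sightings
ole_latest <- function(x) {
  s <- sort(x, decreasing = TRUE)   # s[1] = most extreme
  k <- length(s)
  v <- sum(log((s[1] - s[k]) / (s[1] - s[2:(k - 1)]))) / (k - 1)
  lam_fun <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    exp(lgamma(2 * v + hi) + lgamma(v + lo) - lgamma(v + hi) - lgamma(lo))
  }
  lam <- outer(seq_len(k), seq_len(k), lam_fun)
  li <- solve(lam, rep(1, k))
  sum(li / sum(li) * s)
}

#' Logistic threshold-crossing estimator
#'
#' Fits a binomial GLM of flowering status on DOY and reads the transition
#' off the fitted probability curve evaluated on DOY 1-365.  Before the
#' onset fit, absences after the last observed presence are excluded; before
#' the end fit, absences before the first observed presence are excluded.
#' Onset is the first DOY with fitted probability `>= threshold`; end is the
#' first DOY after the first upward crossing with probability `< threshold`.
#'
#' When the classes are perfectly separated the maximum-likelihood fit
#' diverges; a lightly ridge-penalized fit is then used instead, which keeps
#' the crossing inside the empirical gap between the classes.
#'
#' @param obs An observation data frame.
#' @param threshold Probability threshold in (0, 1).
#' @param which `"onset"` or `"end"`.
#' @return Estimated DOY or `NA` (single-class data after filtering, failed
#'   fit, or threshold never crossed).
#' @export
logistic_transition <- function(obs, threshold, which = c("onset", "end")) {
  which <- match.arg(which)
  d <- obs_doys(obs)
  logit_transition(d$presence, d$absence, threshold, which)
}

logit_transition <- function(pres, abs, threshold, which) {
  f <- filter_status(pres, abs, which)
  if (length(f$pres) == 0L || length(f$abs) == 0L) return(NA_real_)
  doy <- c(f$pres, f$abs)
  y <- rep(c(1, 0), c(length(f$pres), length(f$abs)))
  p <- fit_logit_curve(doy, y)
  if (is.null(p)) return(NA_real_)
  curve_cross(p, threshold, which)
}

# pre-filters shared by the logistic and GAM estimators
filter_status <- function(pres, abs, which) {
  if (length(pres)) {
    if (which == "onset") abs <- abs[abs <= max(pres)]
    else if (which == "end") abs <- abs[abs >= min(pres)]
  }
  list(pres = pres, abs = abs)
}

# fitted binomial-GLM probabilities on DOY 1-365, ridge fallback on separation
fit_logit_curve <- function(doy, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    tryCatch(glm(y ~ doy, family = binomial()), error = function(e) NULL),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!is.null(fit) && !sep && fit$converged)
    return(as.numeric(predict(fit, data.frame(doy = 1:365), type = "response")))
  ridge_logit_curve(doy, y)
}

# ridge-stabilized logistic fit (penalty on the standardized slope only)
ridge_logit_curve <- function(doy, y, lambda = 1e-2) {
  mu <- mean(doy)
  sdv <- sd(doy)
  if (!is.finite(sdv) || sdv == 0) return(NULL)
  z <- (doy - mu) / sdv
  nll <- function(b) {
    eta <- b[1] + b[2] * z
    sum(ifelse(eta > 30, eta, log1p(exp(eta)))) - sum(y * eta) + lambda * b[2]^2
  }
  opt <- tryCatch(optim(c(0, 0), nll, method = "BFGS"), error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  zg <- (1:365 - mu) / sdv
  plogis(opt$par[1] + opt$par[2] * zg)
}

#' Binomial GAM probability curve and its transition dates
#'
#' `gam_fit()` fits a binomial generalized additive model of flowering
#' status on DOY with a thin plate regression spline
#' (`mgcv::gam(flowering ~ s(doy, bs = "tp"), family = binomial)`) after the
#' same pre-filtering as [logistic_transition()] (`which_filter = "peak"`
#' applies no filter), and evaluates the expected probability of flowering
#' on every DOY 1-365.  `gam_transition()` reads onset (first DOY with
#' probability `>= threshold`) or end (first DOY after the curve's peak with
#' probability `< threshold`) off a curve; `gam_peak()` returns the DOY of
#' maximum probability (earliest, on ties).
#'
#' @param obs An observation data frame.
#' @param which_filter `"onset"`, `"end"`, or `"peak"` (no pre-filter).
#' @param min_obs Minimum number of observations required for a fit.
#' @return `gam_fit()`: a `probability_curve` object (list with `doy` and
#'   `p`), or `NULL` when the fit is not possible (single-class data, too
#'   few distinct days, or a failed fit) - the estimate is then unusable.
#' @export
gam_fit <- function(obs, which_filter = c("peak", "onset", "end"),
                    min_obs = 5L) {
  which_filter <- match.arg(which_filter)
  d <- obs_doys(obs)
  gam_curve(d$presence, d$absence, which_filter, min_obs)
}

gam_curve <- function(pres, abs, which_filter, min_obs = 5L) {
  if (which_filter %in% c("onset", "end")) {
    f <- filter_status(pres, abs, which_filter)
    pres <- f$pres; abs <- f$abs
  }
  if (length(pres) == 0L || length(abs) == 0L) return(NULL)
  doy <- c(pres, abs)
  if (length(doy) < min_obs) return(NULL)
  kk <- min(10L, length(unique(doy)) - 1L)
  if (kk < 3L) return(NULL)
  y <- rep(c(1, 0), c(length(pres), length(abs)))
  fit <- tryCatch(
    suppressWarnings(mgcv::gam(y ~ s(doy, bs = "tp", k = kk),
                               family = binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.numeric(predict(fit, data.frame(doy = 1:365), type = "response"))
  if (anyNA(p)) return(NULL)
  probability_curve(p)
}

#' @rdname gam_fit
#' @param p Numeric vector of length 365: expected probability of flowering
#'   on each DOY.
#' @export
probability_curve <- function(p) {
  stopifnot(length(p) == 365L, all(p >= 0 & p <= 1))
  structure(list(doy = 1:365, p = as.numeric(p)), class = "probability_curve")
}

#' @export
print.probability_curve <- function(x, ...) {
  cat("<probability_curve> expected flowering probability on DOY 1-365\n")
  cat(sprintf("  max %.3f at DOY %d\n", max(x$p), which.max(x$p)))
  invisible(x)
}

#' @rdname gam_fit
#' @param curve A `probability_curve`.
#' @param threshold Probability threshold in (0, 1).
#' @param which `"onset"` or `"end"`.
#' @return `gam_transition()`/`gam_peak()`: estimated DOY or `NA`.
#' @export
gam_transition <- function(curve, threshold, which = c("onset", "end")) {
  which <- match.arg(which)
  stopifnot(inherits(curve, "probability_curve"))
  curve_cross(curve$p, threshold, which, after_peak = TRUE)
}

#' @rdname gam_fit
#' @export
gam_peak <- function(curve) {
  stopifnot(inherits(curve, "probability_curve"))
  as.numeric(which.max(curve$p))
}

# threshold crossing on an integer-grid probability curve.
# onset: first DOY with p >= threshold.  end: first DOY with p < threshold
# after the reference point (the curve peak for the GAM rule, the first
# upward crossing for the logistic rule).
curve_cross <- function(p, threshold, which, after_peak = FALSE) {
  if (which == "onset") {
    hit <- which(p >= threshold)
    if (length(hit) == 0L) return(NA_real_)
    return(as.numeric(hit[1L]))
  }
  ref <- if (after_peak) which.max(p) else {
    up <- which(p >= threshold)
    if (length(up) == 0L) return(NA_real_)
    up[1L]
  }
  if (p[ref] < threshold) return(NA_real_)  # curve never attains the threshold
  below <- which(p < threshold)
  below <- below[below > ref]
  if (length(below) == 0L) return(NA_real_)
  as.numeric(below[1L])
}

#' Kaplan-Meier median flowering time
#'
#' Treats each observation as a survival record with time = DOY: a presence
#' is an event ("flowering has happened"), an absence a right-censored
#' record ("not yet flowering as of this day").  The estimate is the first
#' DOY at which the Kaplan-Meier survival curve (fit with
#' `survival::survfit`) drops to 0.5 or below - the median flowering time,
#' used to estimate peak flowering.
#'
#' @param obs An observation data frame.
#' @return Estimated DOY, or `NA` when there is no presence observation or
#'   the survival curve never reaches 0.5.
#' @export
survival_median <- function(obs) {
  d <- obs_doys(obs)
  km_median(d$presence, d$absence)
}

km_median <- function(pres, abs) {
  if (length(pres) == 0L) return(NA_real_)
  time <- c(pres, abs)
  event <- rep(c(1L, 0L), c(length(pres), length(abs)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  hit <- which(fit$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(fit$time[hit[1L]])
}

#' Mean flowering date
#'
#' The arithmetic mean DOY of all flowering presence observations; used to
#' estimate peak flowering.
#'
#' @param presence_doys Numeric vector of presence DOYs.
#' @return Estimated DOY or `NA` when empty.
#' @export
mean_flowering <- function(presence_doys) {
  x <- presence_doys[!is.na(presence_doys)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Apply a named estimator to an observation set
#'
#' Single entry point over all eight estimators, as used by the Monte Carlo
#' driver and the command-line interface.
#'
#' @param obs An observation data frame.
#' @param estimator One of `"first_observed"`, `"last_observed"`,
#'   `"midway"`, `"midway7"`, `"mean_midway"`, `"mean_midway7"`,
#'   `"weibull"`, `"logistic"`, `"gam"`, `"survival"`, `"mean_flowering"`.
#' @param metric `"onset"`, `"peak"`, or `"end"`.
#' @param threshold Probability threshold for the logistic and GAM
#'   estimators (ignored otherwise).
#' @return An object of class `phenodate_estimate`: a list with `estimate`
#'   (DOY or `NA`), `usable`, `estimator`, `metric`, and `threshold`.
#' @examples
#' obs <- data.frame(plant_id = "p1", year = 1995,
#'                   doy = c(180, 186, 190, 201),
#'                   status = c("absent", "present", "present", "absent"))
#' estimate_transition(obs, "midway", "onset")
#' @export
estimate_transition <- function(obs, estimator, metric = c("onset", "peak", "end"),
                                threshold = 0.5) {
  metric <- match.arg(metric)
  d <- obs_doys(obs)
  est <- switch(estimator,
    first_observed = if (metric == "onset") first_observed(obs) else
      stop("first_observed estimates onset only"),
    last_observed = if (metric == "end") last_observed(obs) else
      stop("last_observed estimates end only"),
    midway = if (metric == "onset") midway_onset(obs) else midway_end(obs),
    midway7 = if (metric == "onset") midway_onset(obs, 7) else midway_end(obs, 7),
    mean_midway = mean_midway(obs, NULL, if (metric == "end") "end" else "onset"),
    mean_midway7 = mean_midway(obs, 7, if (metric == "end") "end" else "onset"),
    weibull = weibull_endpoint(d$presence,
                               if (metric == "end") "latest" else "earliest"),
    logistic = logistic_transition(obs, threshold,
                                   if (metric == "end") "end" else "onset"),
    gam = {
      curve <- gam_fit(obs, which_filter = metric)
      if (is.null(curve)) NA_real_
      else if (metric == "peak") gam_peak(curve)
      else gam_transition(curve, threshold, metric)
    },
    survival = survival_median(obs),
    mean_flowering = mean_flowering(d$presence),
    stop("unknown estimator: ", estimator))
  structure(list(estimate = est, usable = !is.na(est), estimator = estimator,
                 metric = metric,
                 threshold = if (estimator %in% c("logistic", "gam") &&
                                 metric != "peak") threshold else NA_real_),
            class = "phenodate_estimate")
}

#' @export
print.phenodate_estimate <- function(x, ...) {
  cat(sprintf("<phenodate_estimate> %s of flowering %s: %s%s\n",
              x$estimator, x$metric,
              if (x$usable) sprintf("DOY %.1f", x$estimate) else "unusable",
              if (!is.na(x$threshold)) sprintf(" (threshold %.2f)", x$threshold)
              else ""))
  invisible(x)
}
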