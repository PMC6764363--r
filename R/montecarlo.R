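# estimator -> metric assignments at each scale (population table: First/Last
# Observed, Mean Midway (7-Day), Weibull, Logistic, GAM for onset/end; GAM,
# Survival, Mean Flowering for peak; individual table: First/Last Observed,
# Midway (7-Day), Weibull, Logistic, GAM for onset/end)
POP_ESTIMATORS <- list(
  onset = c("first_observed", "mean_midway", "mean_midway7", "weibull",
            "logistic", "gam"),
  peak = c("gam", "survival", "mean_flowering"),
  end = c("last_observed", "mean_midway", "mean_midway7", "weibull",
          "logistic", "gam"))
IND_ESTIMATORS <- list(
  onset = c("first_observed", "midway", "midway7", "weibull", "logistic", "gam"),
  end = c("last_observed", "midway", "midway7", "weibull", "logistic", "gam"))

# one row per estimator x metric (x threshold for logistic/gam transitions)
build_plan <- function(registry, estimators, metrics, thresholds) {
  rows <- list()
  for (metric in metrics) {
    for (est in intersect(registry[[metric]], estimators)) {
      th <- if (est %in% c("logistic", "gam") && metric != "peak")
        thresholds else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, metric = metric, threshold = th,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no estimator/metric combinations selected")
  do.call(rbind, rows)
}

# evaluate every plan row on one drawn sample (vectors, no data frames)
eval_plan <- function(plan, pres, abs, pres_plant = NULL, abs_plant = NULL) {
  vals <- rep(NA_real_, nrow(plan))
  curves <- list()   # cached GAM curves / logistic probability grids per filter
  for (i in seq_len(nrow(plan))) {
    est <- plan$estimator[i]; metric <- plan$metric[i]; th <- plan$threshold[i]
    vals[i] <- switch(est,
      first_observed = if (length(pres)) min(pres) else NA_real_,
      last_observed = if (length(pres)) max(pres) else NA_real_,
      midway = if (metric == "onset") mid_onset(pres, abs) else mid_end(pres, abs),
      midway7 = if (metric == "onset") mid_onset(pres, abs, 7) else mid_end(pres, abs, 7),
      mean_midway = mean_mid_vec(pres, abs, pres_plant, abs_plant, NULL, metric),
      mean_midway7 = mean_mid_vec(pres, abs, pres_plant, abs_plant, 7, metric),
      weibull = weibull_endpoint(pres, if (metric == "end") "latest" else "earliest"),
      survival = km_median(pres, abs),
      mean_flowering = mean_flowering(pres),
      logistic = {
        key <- paste0("logit_", metric)
        if (is.null(curves[[key]])) {
          f <- filter_status(pres, abs, metric)
          curves[[key]] <- if (length(f$pres) && length(f$abs))
            fit_logit_curve(c(f$pres, f$abs),
                            rep(c(1, 0), c(length(f$pres), length(f$abs))))
          if (is.null(curves[[key]])) curves[[key]] <- NA
        }
        p <- curves[[key]]
        if (length(p) == 365L) curve_cross(p, th, metric) else NA_real_
      },
      gam = {
        key <- paste0("gam_", metric)
        if (is.null(curves[[key]]))
          curves[[key]] <- gam_curve(pres, abs, metric) %||% NA
        cv <- curves[[key]]
        if (!inherits(cv, "probability_curve")) NA_real_
        else if (metric == "peak") gam_peak(cv)
        else gam_transition(cv, th, metric)
      })
  }
  vals
}

derive_seed <- function(seed, i_scenario, i_unit = 0L) {
  as.integer((abs(as.numeric(seed)) + 7919 * i_scenario + 104729 * i_unit) %%
               2147483647)
}

#' Run the population-scale Monte Carlo experiment
#'
#' For every scenario (sample size x presence fraction), every year, and
#' every replicate, draws one population status sample and applies the
#' selected estimators to it.  Replicate draws within a scenario-year use a
#' seed derived deterministically from `seed` (see Details), so the full
#' record set is reproducible.
#'
#' @param schedules A schedule data frame (the ground truth).
#' @param n_obs Vector of sample sizes (default 10, 50, 100).
#' @param presence_fraction Vector of presence fractions (default 0.25,
#'   0.50, 0.75).
#' @param n_replicates Replicates per scenario-year (default 1000).
#' @param estimators Estimator names to run; defaults to all population
#'   estimators.  Each runs only for the metrics it supports.
#' @param metrics Metrics to estimate (subset of onset/peak/end).
#' @param thresholds Probability thresholds evaluated for the logistic and
#'   GAM estimators.
#' @param seed Integer base seed.
#' @return A record data frame: `scale`, `n_obs`, `presence_fraction`,
#'   `year`, `plant_id` (`NA` at population scale), `replicate`,
#'   `estimator`, `metric`, `threshold`, `estimate`, `usable`.  Exactly
#'   `length(years) * n_replicates` rows per estimator x metric x threshold
#'   x scenario, unusable replicates included.
#' @details The RNG stream of scenario `s`, year-index `y` is seeded with
#'   `(seed + 7919 s + 104729 y) mod (2^31 - 1)`.  A sampling pool too small
#'   for a scenario yields unusable records, not an error.
#' @export
run_population_experiment <- function(schedules,
                                      n_obs = c(10L, 50L, 100L),
                                      presence_fraction = c(0.25, 0.50, 0.75),
                                      n_replicates = 1000L,
                                      estimators = unique(unlist(POP_ESTIMATORS)),
                                      metrics = c("onset", "peak", "end"),
                                      thresholds = c(0.05, 0.25, 0.50, 0.75, 0.95),
                                      seed = 1L) {
  plan <- build_plan(POP_ESTIMATORS, estimators, metrics, thresholds)
  years <- sort(unique(schedules$year))
  scen <- expand.grid(n_obs = n_obs, presence_fraction = presence_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  pools <- lapply(years, function(y) {
    m <- expand_daily_status(schedules, y)
    list(np = nrow(m), pres = which(m), abs = which(!m))
  })
  blocks <- vector("list", nrow(scen) * length(years))
  bi <- 0L
  for (s in seq_len(nrow(scen))) {
    n <- scen$n_obs[s]
    n_pres <- presence_count(n, scen$presence_fraction[s])
    n_abs <- n - n_pres
    for (yi in seq_along(years)) {
      set.seed(derive_seed(seed, s, yi))
      pool <- pools[[yi]]
      feasible <- length(pool$pres) >= n_pres && length(pool$abs) >= n_abs
      est <- matrix(NA_real_, n_replicates, nrow(plan))
      if (feasible) {
        for (r in seq_len(n_replicates)) {
          pi <- pool$pres[sample.int(length(pool$pres), n_pres)]
          ai <- pool$abs[sample.int(length(pool$abs), n_abs)]
          est[r, ] <- eval_plan(plan,
                                pres = (pi - 1L) %/% pool$np + 1L,
                                abs = (ai - 1L) %/% pool$np + 1L,
                                pres_plant = (pi - 1L) %% pool$np + 1L,
                                abs_plant = (ai - 1L) %% pool$np + 1L)
        }
      }
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        scale = "population", n_obs = n,
        presence_fraction = scen$presence_fraction[s],
        year = years[yi], plant_id = NA_character_,
        replicate = rep(seq_len(n_replicates), times = nrow(plan)),
        estimator = rep(plan$estimator, each = n_replicates),
        metric = rep(plan$metric, each = n_replicates),
        threshold = rep(plan$threshold, each = n_replicates),
        estimate = as.vector(est),
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, blocks)
  rec$usable <- !is.na(rec$estimate)
  rec
}

#' Run the individual-scale Monte Carlo experiment
#'
#' Applies the individual estimators to repeated status samples of single
#' plants.  Only plant-years flowering strictly more than
#' `min_flowering_days` days are used (the schedules are filtered with
#' [filter_long_flowering()] internally).
#'
#' @inheritParams run_population_experiment
#' @param n_obs Vector of per-plant sample sizes (default 5, 10, 20).
#' @param n_replicates Replicates per plant-year (default 20).
#' @param min_flowering_days Strict minimum flowering duration (default 20).
#' @return A record data frame as in [run_population_experiment()], with
#'   `plant_id` filled in; `length(plant-years) * n_replicates` rows per
#'   estimator x metric x threshold x scenario.
#' @export
run_individual_experiment <- function(schedules,
                                      n_obs = c(5L, 10L, 20L),
                                      presence_fraction = c(0.25, 0.50, 0.75),
                                      n_replicates = 20L,
                                      estimators = unique(unlist(IND_ESTIMATORS)),
                                      metrics = c("onset", "end"),
                                      thresholds = c(0.05, 0.25, 0.50, 0.75, 0.95),
                                      min_flowering_days = 20L,
                                      seed = 1L) {
  plan <- build_plan(IND_ESTIMATORS, estimators,
                     setdiff(metrics, "peak"), thresholds)
  sched <- filter_long_flowering(schedules, min_flowering_days)
  if (nrow(sched) == 0L) stop("no plant-years flowering more than ",
                              min_flowering_days, " days")
  scen <- expand.grid(n_obs = n_obs, presence_fraction = presence_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  n_py <- nrow(sched)
  blocks <- vector("list", nrow(scen))
  for (s in seq_len(nrow(scen))) {
    set.seed(derive_seed(seed, s))
    n <- scen$n_obs[s]
    n_pres <- presence_count(n, scen$presence_fraction[s])
    n_abs <- n - n_pres
    est <- matrix(NA_real_, n_py * n_replicates, nrow(plan))
    row <- 0L
    for (j in seq_len(n_py)) {
      win <- sched$start_doy[j]:sched$end_doy[j]
      out <- setdiff(1:365, win)
      feasible <- length(win) >= n_pres && length(out) >= n_abs
      for (r in seq_len(n_replicates)) {
        row <- row + 1L
        if (!feasible) next
        pres <- win[sample.int(length(win), n_pres)]
        abs_ <- out[sample.int(length(out), n_abs)]
        est[row, ] <- eval_plan(plan, pres, abs_)
      }
    }
    blocks[[s]] <- data.frame(
      scale = "individual", n_obs = n,
      presence_fraction = scen$presence_fraction[s],
      year = rep(rep(sched$year, each = n_replicates), times = nrow(plan)),
      plant_id = rep(rep(sched$plant_id, each = n_replicates), times = nrow(plan)),
      replicate = rep(rep(seq_len(n_replicates), times = n_py), times = nrow(plan)),
      estimator = rep(plan$estimator, each = n_py * n_replicates),
      metric = rep(plan$metric, each = n_py * n_replicates),
      threshold = rep(plan$threshold, each = n_py * n_replicates),
      estimate = as.vector(est),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, blocks)
  rec$usable <- !is.na(rec$estimate)
  rec
}

#' Signed errors of usable estimates
#'
#' Joins each usable estimate with its ground truth and returns the signed
#' error in days (positive = estimate later than truth).  Unusable records
#' are excluded; a usable record with no matching truth is an error.
#'
#' @param records A record data frame from the experiment runners.
#' @param truths The truth tables from [true_metrics_table()].
#' @return The usable records with `truth` and `error` columns added.
#' @export
compute_errors <- function(records, truths) {
  use <- records[records$usable, , drop = FALSE]
  if (nrow(use) == 0L) {
    use$truth <- numeric(0); use$error <- numeric(0)
    return(use)
  }
  truth <- rep(NA_real_, nrow(use))
  is_pop <- use$scale == "population"
  if (any(is_pop)) {
    pop <- truths$population
    for (metric in unique(use$metric[is_pop])) {
      sel <- is_pop & use$metric == metric
      truth[sel] <- pop[[metric]][match(use$year[sel], pop$year)]
    }
  }
  if (any(!is_pop)) {
    ind <- truths$individual
    key <- paste(ind$plant_id, ind$year)
    for (metric in unique(use$metric[!is_pop])) {
      sel <- !is_pop & use$metric == metric
      truth[sel] <- ind[[metric]][match(paste(use$plant_id[sel], use$year[sel]), key)]
    }
  }
  if (anyNA(truth)) stop("missing ground truth for ", sum(is.na(truth)),
                         " usable estimate(s)")
  use$truth <- truth
  use$error <- use$estimate - truth
  use
}

#' Scenario summaries: R-squared, error quantiles, usable rate
#'
#' Pools errors across years (population scale) or plant-years (individual
#' scale) within each estimator x metric x scenario (x threshold) cell and
#' computes the comparison statistics: R-squared between usable estimates
#' and their true dates, the median signed error, the 2.5% and 97.5% error
#' quantiles (type-7 linear interpolation), and the usable rate.
#'
#' @inheritParams compute_errors
#' @param r_squared `"pearson"` (squared Pearson correlation between
#'   estimates and truths; the default) or `"identity"` (1 - SSE/SST about
#'   the 1:1 line).
#' @return A data frame with one row per cell: `estimator`, `metric`,
#'   `n_obs`, `presence_fraction`, `threshold`, `n_total`, `n_usable`,
#'   `usable_rate`, `r_squared`, `median_error`, `q025_error`,
#'   `q975_error`.  Cells with fewer than two usable pairs get `NA`
#'   R-squared but keep their usable rate.
#' @export
summarize_scenarios <- function(records, truths,
                                r_squared = c("pearson", "identity")) {
  r_squared <- match.arg(r_squared)
  err <- compute_errors(records, truths)
  key_of <- function(d) paste(d$estimator, d$metric, d$n_obs,
                              d$presence_fraction, d$threshold, sep = "\r")
  totals <- table(key_of(records))
  cells <- split(err, key_of(err))
  all_keys <- sort(names(totals))
  out <- lapply(all_keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    cell <- cells[[k]]
    n_tot <- as.integer(totals[[k]])
    n_use <- if (is.null(cell)) 0L else nrow(cell)
    r2 <- med <- q025 <- q975 <- NA_real_
    if (n_use >= 1L) {
      med <- median(cell$error)
      q <- quantile(cell$error, c(0.025, 0.975), names = FALSE, type = 7)
      q025 <- q[1L]; q975 <- q[2L]
    }
    if (n_use >= 2L) {
      if (r_squared == "pearson") {
        if (sd(cell$estimate) > 0 && sd(cell$truth) > 0)
          r2 <- cor(cell$estimate, cell$truth)^2
        else if (all(cell$error == 0)) r2 <- 1
      } else {
        sst <- sum((cell$truth - mean(cell$truth))^2)
        if (sst > 0) r2 <- 1 - sum(cell$error^2) / sst
        else if (all(cell$error == 0)) r2 <- 1
      }
    }
    data.frame(estimator = parts[1L], metric = parts[2L],
               n_obs = as.numeric(parts[3L]),
               presence_fraction = as.numeric(parts[4L]),
               threshold = suppressWarnings(as.numeric(parts[5L])),
               n_total = n_tot, n_usable = n_use,
               usable_rate = n_use / n_tot,
               r_squared = r2, median_error = med,
               q025_error = q025, q975_error = q975,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the best probability threshold per estimator, metric, and scenario
#'
#' For threshold-based estimators (logistic, GAM) the study evaluates five
#' probability thresholds and keeps, for each estimator x metric x sample
#' size x presence fraction, the one with the highest R-squared (ties go to
#' the lower threshold).  Rows without a threshold pass through unchanged.
#'
#' @param summaries A summary data frame from [summarize_scenarios()].
#' @return The summaries reduced to one row per estimator x metric x
#'   scenario, with a `selected_threshold` column (`NA` where no threshold
#'   applies, or where no candidate had a computable R-squared).
#' @export
select_threshold <- function(summaries) {
  has_th <- !is.na(summaries$threshold)
  keep <- summaries[!has_th, , drop = FALSE]
  if (nrow(keep)) keep$selected_threshold <- NA_real_
  th <- summaries[has_th, , drop = FALSE]
  if (nrow(th)) {
    grp <- paste(th$estimator, th$metric, th$n_obs, th$presence_fraction,
                 sep = "\r")
    picked <- lapply(split(th, grp), function(g) {
      g <- g[order(g$threshold), , drop = FALSE]
      if (all(is.na(g$r_squared))) {
        row <- g[1L, , drop = FALSE]
        row$threshold <- NA_real_
        row$selected_threshold <- NA_real_
        return(row)
      }
      row <- g[which.max(g$r_squared), , drop = FALSE]  # first max = lower th
      row$selected_threshold <- row$threshold
      row
    })
    th <- do.call(rbind, picked)
    rownames(th) <- NULL
  } else {
    th$selected_threshold <- numeric(0)
  }
  out <- rbind(keep, th)
  rownames(out) <- NULL
  out[order(out$estimator, out$metric, out$n_obs, out$presence_fraction), ,
      drop = FALSE]
}

#' Flag summaries with too few usable estimates
#'
#' Cells where fewer than `min_usable_rate` (default 1%) of the random
#' samples produced a usable estimate are flagged as excluded from the
#' estimator comparison; they remain in the table.
#'
#' @param summaries A summary data frame.
#' @param min_usable_rate Exclusion cutoff on the usable rate.
#' @return The summaries with a logical `excluded` column added.
#' @export
apply_exclusion_rules <- function(summaries, min_usable_rate = 0.01) {
  summaries$excluded <- summaries$usable_rate < min_usable_rate
  summaries
}

#' Run the full study from a configuration
#'
#' Generates the synthetic population, runs the population- and
#' individual-scale Monte Carlo experiments, and produces threshold-selected,
#' exclusion-flagged scenario summaries.
#'
#' @param config A configuration list from [load_config()] /
#'   [default_config()].
#' @param seed Base seed; overrides `config$seed` when given.
#' @param estimators_population,estimators_individual Optional estimator
#'   subsets (defaults: all).
#' @return A list with `schedules`, `truths`, `records` (list of
#'   `population`, `individual`), and `summaries` (list of `population`,
#'   `individual`), plus the resolved `config` and `seed`.
#' @export
run_study <- function(config = default_config(), seed = NULL,
                      estimators_population = unique(unlist(POP_ESTIMATORS)),
                      estimators_individual = unique(unlist(IND_ESTIMATORS))) {
  seed <- as.integer(seed %||% config$seed)
  gen <- config$generator
  gen$seed <- derive_seed(seed, 0L)
  schedules <- generate_schedules(do.call(generator_params, gen))
  truths <- true_metrics_table(schedules)
  pop <- run_population_experiment(
    schedules, n_obs = config$population$n_obs,
    presence_fraction = config$population$presence_fraction,
    n_replicates = config$population$n_replicates,
    estimators = estimators_population, thresholds = config$thresholds,
    seed = derive_seed(seed, 1L))
  ind <- run_individual_experiment(
    schedules, n_obs = config$individual$n_obs,
    presence_fraction = config$individual$presence_fraction,
    n_replicates = config$individual$n_replicates,
    estimators = estimators_individual, thresholds = config$thresholds,
    min_flowering_days = config$individual$min_flowering_days,
    seed = derive_seed(seed, 2L))
  summ <- lapply(list(population = pop, individual = ind), function(rec)
    apply_exclusion_rules(select_threshold(
      summarize_scenarios(rec, truths, config$r_squared))))
  list(schedules = schedules, truths = truths,
       records = list(population = pop, individual = ind),
       summaries = summ, config = config, seed = seed)
}
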