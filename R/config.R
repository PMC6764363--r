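#' Study configuration
#'
#' `default_config()` returns the full default study configuration:
#' the synthetic-generator parameters, the population-scale scenario grid
#' (sample sizes 10/50/100, presence fractions 25/50/75%, 1,000 replicates),
#' the individual-scale grid (sample sizes 5/10/20, same fractions, 20
#' replicates, plants flowering more than 20 days), and the probability
#' threshold grid 0.05/0.25/0.50/0.75/0.95 used by the logistic and GAM
#' estimators.  `load_config()` reads a YAML (or JSON) file and merges it
#' over these defaults; an empty or missing file yields the defaults.
#'
#' @param path Path to a YAML/JSON configuration file, or `NULL` for
#'   defaults.  Unknown keys trigger a warning; invalid values an error.
#' @return A nested configuration list with elements `generator`,
#'   `population`, `individual`, `thresholds`, `r_squared`, and `seed`.
#' @examples
#' cfg <- default_config()
#' cfg$population$n_obs
#' @export
default_config <- function() {
  list(
    generator = as.list(generator_params()),
    population = list(
      n_obs = c(10L, 50L, 100L),
      presence_fraction = c(0.25, 0.50, 0.75),
      n_replicates = 1000L
    ),
    individual = list(
      n_obs = c(5L, 10L, 20L),
      presence_fraction = c(0.25, 0.50, 0.75),
      n_replicates = 20L,
      min_flowering_days = 20L
    ),
    thresholds = c(0.05, 0.25, 0.50, 0.75, 0.95),
    r_squared = "pearson",
    seed = 1L
  )
}

#' @rdname default_config
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user, prefix = NULL)
  }
  validate_config(cfg)
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base)) {
      warning("unknown configuration key: ", full, call. = FALSE)
      next
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk_pos_int <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 1) || any(x != round(x)))
      stop(what, " must be positive integer(s)", call. = FALSE)
    as.integer(x)
  }
  chk_frac <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x <= 0) || any(x >= 1))
      stop(what, " must lie strictly in (0, 1)", call. = FALSE)
    x
  }
  for (scale in c("population", "individual")) {
    cfg[[scale]]$n_obs <- chk_pos_int(cfg[[scale]]$n_obs, paste0(scale, "$n_obs"))
    cfg[[scale]]$presence_fraction <-
      chk_frac(cfg[[scale]]$presence_fraction, paste0(scale, "$presence_fraction"))
    cfg[[scale]]$n_replicates <-
      chk_pos_int(cfg[[scale]]$n_replicates, paste0(scale, "$n_replicates"))
  }
  cfg$individual$min_flowering_days <-
    chk_pos_int(cfg$individual$min_flowering_days, "individual$min_flowering_days")
  cfg$thresholds <- chk_frac(cfg$thresholds, "thresholds")
  if (!cfg$r_squared %in% c("pearson", "identity"))
    stop("r_squared must be 'pearson' or 'identity'", call. = FALSE)
  cfg$generator <- as.list(do.call(generator_params, cfg$generator))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write the resolved configuration and seed of a run to a machine-readable log
#'
#' @param cfg A configuration list.
#' @param seed The seed actually used.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(cfg, seed, path) {
  cfg$seed <- as.integer(seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
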