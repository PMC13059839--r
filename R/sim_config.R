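#' Configuration for a synthetic cluster-randomised mortality trial
#'
#' Defines the true data-generating process of a two-arm cluster-randomised
#' trial of biannual MDA in infants. Defaults reflect the design of a large
#' West African infant-mortality MDA trial: roughly 500 primary-care catchment
#' clusters randomised 2:1 to treatment versus placebo, an assumed control-arm
#' mortality rate of 10 deaths per 1000 person-years among age-eligible
#' (30-364 day old) children, a between-cluster coefficient of variation of
#' 0.33 for the true cluster rates, and MDA rounds every 182 days.
#'
#' @param n_clusters total number of clusters randomised.
#' @param allocation_ratio integer pair (treated:control), default `c(2, 1)`.
#' @param baseline_rate control-arm death rate per person-year among
#'   age-eligible children. Default 0.01 (10 per 1000 person-years).
#' @param effect_irr true multiplicative treatment effect on the eligible-age
#'   rate; 1 is the null, 0.84 a 16 percent relative reduction.
#' @param cv coefficient of variation (sd/mean) of true cluster-level rates
#'   within an arm.
#' @param births_per_cluster_per_round expected live births per cluster per
#'   inter-round interval.
#' @param n_rounds number of biannual MDA rounds.
#' @param round_interval_days days between MDA rounds (and between censuses).
#' @param sensitivity_bh probability that a true death is reported in the
#'   birth-history interview.
#' @param move_prob per inter-census-interval probability that a child
#'   out-migrates.
#' @param background_rate death rate per person-year outside the 30-364 day
#'   eligibility ages (neonates and children past 1 year). Mortality in the
#'   first month of life is typically several-fold higher than postneonatal
#'   mortality; the default of 0.03 keeps that ordering.
#' @param unknown_prob per child-round probability that an alive child is
#'   recorded with unknown vital status at a census (missed household).
#' @param seed integer RNG seed. All randomness in the generator flows from
#'   this seed through independent sub-streams for cluster rates, births,
#'   deaths, migration/census noise and birth-history degradation.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_clusters = 30, births_per_cluster_per_round = 20)
#' cfg$baseline_rate
sim_config <- function(n_clusters = 516L,
                       allocation_ratio = c(2L, 1L),
                       baseline_rate = 0.01,
                       effect_irr = 1.0,
                       cv = 0.33,
                       births_per_cluster_per_round = 90L,
                       n_rounds = 4L,
                       round_interval_days = 182L,
                       sensitivity_bh = 0.85,
                       move_prob = 0.05,
                       background_rate = 0.03,
                       unknown_prob = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    allocation_ratio = as.integer(allocation_ratio),
    baseline_rate = baseline_rate,
    effect_irr = effect_irr,
    cv = cv,
    births_per_cluster_per_round = as.integer(births_per_cluster_per_round),
    n_rounds = as.integer(n_rounds),
    round_interval_days = as.integer(round_interval_days),
    sensitivity_bh = sensitivity_bh,
    move_prob = move_prob,
    background_rate = background_rate,
    unknown_prob = unknown_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_clusters < 2L) stop("invalid config: need at least 2 clusters")
  if (length(cfg$allocation_ratio) != 2L || any(cfg$allocation_ratio <= 0L))
    stop("invalid config: allocation_ratio must be two positive counts")
  if (cfg$baseline_rate < 0 || cfg$background_rate < 0 || cfg$effect_irr < 0)
    stop("invalid config: rates must be >= 0")
  if (cfg$cv < 0) stop("invalid config: cv must be >= 0")
  if (cfg$sensitivity_bh < 0 || cfg$sensitivity_bh > 1)
    stop("invalid config: sensitivity_bh must lie in [0, 1]")
  if (cfg$move_prob < 0 || cfg$move_prob > 1 ||
      cfg$unknown_prob < 0 || cfg$unknown_prob > 1)
    stop("invalid config: probabilities must lie in [0, 1]")
  if (cfg$n_rounds < 1L || cfg$round_interval_days < 1L)
    stop("invalid config: need >= 1 round with a positive interval")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat(sprintf("  clusters: %d (%d:%d allocation)\n", x$n_clusters,
              x$allocation_ratio[1], x$allocation_ratio[2]))
  cat(sprintf("  control rate: %g/PY, effect IRR: %g, cv: %g\n",
              x$baseline_rate, x$effect_irr, x$cv))
  cat(sprintf("  %d MDA rounds every %d days, %d births/cluster/round\n",
              x$n_rounds, x$round_interval_days,
              x$births_per_cluster_per_round))
  cat(sprintf("  birth-history sensitivity: %g, move prob: %g, seed: %d\n",
              x$sensitivity_bh, x$move_prob, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration
#'
#' Round-trips a [sim_config()] through YAML so a study configuration can be
#' versioned alongside results.
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

# Derive independent sub-seeds (one per generator component) from the master
# seed, so e.g. the migration stream can be varied without disturbing deaths.
component_seeds <- function(seed) {
  r <- local_rng(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  r()
  setNames(s, c("rates", "births", "deaths", "migration", "census",
                "degrade"))
}

# Set the RNG to `seed` and return a restore function. Keeps generator
# functions from clobbering the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
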