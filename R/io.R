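#' Read and validate a child record CSV
#'
#' Column dictionary: `child_id` (character), `cluster_id` (integer),
#' `arm` ("azithromycin"/"placebo"), `dob` (integer day index from study
#' start), optional `dod`, `moved_day` (integer day or empty), optional
#' `sex`, `region`, `csps_type`. Validation failures name the offending
#' column and rows.
#'
#' @param path CSV path.
#' @return data.table of child records.
#' @export
read_children_csv <- function(path) {
  x <- fread(path, na.strings = c("", "NA"))
  need <- c("child_id", "cluster_id", "arm", "dob")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  bad_arm <- which(!x$arm %in% c("azithromycin", "placebo"))
  if (length(bad_arm))
    stop("column 'arm': invalid values at row(s) ",
         paste(utils::head(bad_arm, 5L), collapse = ", "))
  if ("dod" %in% names(x)) {
    bad <- which(!is.na(x$dod) & x$dod <= x$dob)
    if (length(bad))
      stop("column 'dod': death on/before birth at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  x[]
}

#' Write child records, schedules and aggregates as CSV
#'
#' @param x table to write.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  fwrite(as.data.table(x), path)
  invisible(path)
}

#' Read a cluster schedule CSV (`cluster_id`, `round`, `date`)
#' @param path CSV path.
#' @return data.table.
#' @export
read_schedule_csv <- function(path) {
  x <- fread(path)
  miss <- setdiff(c("cluster_id", "date"), names(x))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  x[]
}

#' Export a synthetic trial to CSV files
#'
#' Writes the child table, MDA schedule, census status stream, cluster frame
#' and the generating configuration (YAML) into a directory.
#'
#' @param trial a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return named vector of the paths written.
#' @export
export_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    children = file.path(dir, "children.csv"),
    mda = file.path(dir, "mda_schedule.csv"),
    census = file.path(dir, "census_status.csv"),
    clusters = file.path(dir, "clusters.csv"),
    config = file.path(dir, "sim_config.yaml")
  )
  write_table_csv(trial$children, paths["children"])
  write_table_csv(trial$mda, paths["mda"])
  write_table_csv(trial$census, paths["census"])
  write_table_csv(trial$clusters, paths["clusters"])
  write_sim_config(trial$config, paths["config"])
  paths
}

#' Run the whole analysis pipeline on a synthetic trial
#'
#' Ties the stages together: simulate a trial, degrade it to the
#' birth-history stream, accrue deaths and person-time under both
#' enumeration procedures, compare arms (IRR with robust and permutation
#' inference, bootstrap IRD), run the probabilistic bias analysis on the
#' birth-history IRD, estimate synthetic-cohort cumulative mortality per
#' arm, and analyse cause-specific mortality on simulated verbal-autopsy
#' output. All randomness flows from `cfg$seed` and `seed`; rerunning with
#' the same configuration reproduces the bundle exactly.
#'
#' @param cfg a [sim_config()].
#' @param bias a [bias_params()]; `NULL` uses the package default prior.
#' @param n_boot,n_perm replicate counts for the resampling inference.
#' @param seed analysis-stage RNG seed (distinct from the generator seed).
#' @param out_dir if non-`NULL`, write aggregates (CSV) and results (JSON)
#'   there.
#' @return list: `trial`, `aggregates` (both methods, stacked), `birth_history`
#'   and `census` comparison results, `bias`, `cohort`, `causes`, `seeds`.
#' @export
run_pipeline <- function(cfg, bias = NULL, n_boot = 2000L, n_perm = 2000L,
                         seed = 1L, out_dir = NULL) {
  validate_sim_config(cfg)
  if (is.null(bias)) bias <- bias_params(seed = seed + 7L)

  trial <- simulate_trial(cfg)
  bh_children <- degrade_to_birth_history(trial)
  end_day <- max(trial$census_dates)

  agg_bh <- accrue_birth_history(bh_children, trial$mda,
                                 clusters = trial$clusters)
  agg_cs <- accrue_census(trial$children, trial$census,
                          clusters = trial$clusters)
  aggregates <- rbind(agg_bh, agg_cs)

  res_bh <- compare_arms(agg_bh, n_boot = n_boot, n_perm = n_perm,
                         seed = seed)
  res_cs <- compare_arms(agg_cs, n_boot = n_boot, n_perm = n_perm,
                         seed = seed + 1L)

  bias_res <- run_bias_analysis(agg_bh, bias, sd_ird = res_bh$ird$sd_boot)

  cohort <- synthetic_cohort(bh_children,
                             window = c(end_day - 3L * 365L, end_day + 1L),
                             n_boot = min(n_boot, 500L), seed = seed + 2L)

  va <- simulate_cause_assignments(trial, seed = seed + 3L)
  flt <- filter_causes(va)
  causes <- cause_irrs(flt, agg_bh)

  bundle <- list(trial = trial, aggregates = aggregates,
                 birth_history = res_bh, census = res_cs,
                 bias = bias_res, cohort = cohort, causes = causes,
                 seeds = c(config = cfg$seed, analysis = seed))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(aggregates, file.path(out_dir, "aggregates.csv"))
    results <- list(
      seeds = bundle$seeds,
      birth_history = summarise_comparison(res_bh),
      census = summarise_comparison(res_cs),
      bias = bias_res[c("ird_corrected", "ui_low", "ui_high",
                        "ird_uncorrected", "sd_ird", "n_iter")],
      cohort = as.data.frame(cohort),
      causes = as.data.frame(causes)
    )
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

summarise_comparison <- function(res) {
  list(
    rate_treated = res$rate_treated, rate_control = res$rate_control,
    irr = res$irr$irr, irr_ci = c(res$irr$ci_low, res$irr$ci_high),
    p_wald = res$irr$p_wald, p_permutation = res$irr$p_permutation,
    ird = res$ird$ird, ird_ci = c(res$ird$ci_low, res$ird$ci_high),
    deaths = res$irr$deaths, person_years = res$irr$person_years,
    n_clusters = res$irr$n_clusters
  )
}
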