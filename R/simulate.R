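#' Draw true cluster-level mortality rates
#'
#' Between-cluster heterogeneity follows a gamma distribution moment-matched
#' to the arm mean and the configured coefficient of variation: within an arm
#' with mean rate m, rates are Gamma(shape = 1/cv^2, scale = m cv^2), so
#' sd/mean = cv exactly. With `cv = 0` the distribution degenerates to the
#' arm mean. Treated clusters have mean `baseline_rate * effect_irr`.
#'
#' @param cfg a [sim_config()].
#' @param arms character vector of arm labels ("azithromycin"/"placebo"), one
#'   per cluster. If `NULL`, an allocation respecting `cfg$allocation_ratio`
#'   is generated.
#' @param seed RNG seed; defaults to the rates sub-stream of `cfg$seed`.
#' @return numeric vector of per-cluster rates (deaths per person-year), with
#'   the arm labels as an attribute when arms were generated here.
#' @export
draw_cluster_rates <- function(cfg, arms = NULL, seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(seed)) seed <- component_seeds(cfg$seed)[["rates"]]
  restore <- local_rng(seed)
  on.exit(restore())

  if (is.null(arms)) arms <- assign_arms(cfg)
  m <- ifelse(arms == "azithromycin",
              cfg$baseline_rate * cfg$effect_irr, cfg$baseline_rate)
  if (cfg$cv == 0) {
    rates <- m
  } else {
    shape <- 1 / cfg$cv^2
    rates <- rgamma(length(m), shape = shape, scale = m / shape)
  }
  attr(rates, "arms") <- arms
  rates
}

# 2:1 (or configured) allocation: exact arm counts, random order.
assign_arms <- function(cfg) {
  n <- cfg$n_clusters
  a <- cfg$allocation_ratio
  n_treat <- round(n * a[1] / sum(a))
  sample(rep(c("azithromycin", "placebo"), c(n_treat, n - n_treat)))
}

# Age at death (days, continuous) under a piecewise-constant hazard:
# `hb` per day outside ages [30, 365), `hc` per day inside. Vectorised
# inverse-CDF sampling; Inf when the cumulative hazard never reaches the
# exponential draw (both hazards zero).
piecewise_age_at_death <- function(n, hb, hc) {
  e <- rexp(n)
  h1 <- 30 * hb          # cumulative hazard at age 30
  h2 <- h1 + 335 * hc    # cumulative hazard at age 365
  age <- rep(Inf, n)
  in1 <- hb > 0 & e < h1
  age[in1] <- e[in1] / hb[in1]
  in2 <- !in1 & hc > 0 & e < h2
  age[in2] <- 30 + (e[in2] - h1[in2]) / hc[in2]
  in3 <- !in1 & !in2 & hb > 0
  age[in3] <- 365 + (e[in3] - h2[in3]) / hb[in3]
  age
}

#' Simulate a complete synthetic trial
#'
#' Generates one underlying truth — cluster rates, live births, death and
#' out-migration times — and derives from it the census observation stream
#' (vital status alive/dead/moved/unknown at each census round). Births are
#' uniform over the window starting 365 days before the first MDA round (so
#' the first round already has age-eligible children) and ending at the final
#' census. A child's death clock runs at the cluster's rate while aged 30-364
#' days and at `background_rate` otherwise. Movers are censored at their move
#' day and never return; a death after out-migration is not part of the
#' trial's truth.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `trial_dataset`: a list with elements
#'   `children` (one row per child: id, cluster, arm, sex, region, csps_type,
#'   dob, dod, moved_day — day indices from study start), `census` (long
#'   table child x round with date and status), `census_dates`, `mda`
#'   (cluster x round MDA dates), `clusters` (cluster frame with arm and true
#'   rate) and `config`.
#' @export
simulate_trial <- function(cfg) {
  validate_sim_config(cfg)
  seeds <- component_seeds(cfg$seed)
  dl <- cfg$round_interval_days
  end_day <- cfg$n_rounds * dl
  census_dates <- seq(0L, end_day, by = dl)

  rates <- draw_cluster_rates(cfg, seed = seeds[["rates"]])
  arms <- attr(rates, "arms")
  clusters <- data.table(
    cluster_id = seq_len(cfg$n_clusters), arm = arms,
    true_rate = as.numeric(rates)
  )
  # cluster descriptor labels get their own derived stream
  restore <- local_rng(seeds[["rates"]] %% 1000003L + 7L)
  clusters[, region := sample(c("Sud-Ouest", "Centre-Est", "Hauts-Bassins"),
                              .N, replace = TRUE)]
  clusters[, csps_type := sample(c("rural", "urban", "mixed"), .N,
                                 replace = TRUE, prob = c(0.8, 0.1, 0.1))]
  restore()

  # births: uniform over [-365, end_day)
  restore <- local_rng(seeds[["births"]])
  birth_span <- end_day + 365L
  lambda_births <- cfg$births_per_cluster_per_round * birth_span / dl
  n_births <- rpois(cfg$n_clusters, lambda_births)
  children <- data.table(
    cluster_id = rep(clusters$cluster_id, n_births)
  )
  n_total <- nrow(children)
  children[, child_id := sprintf("c%07d", seq_len(n_total))]
  children[, dob := as.integer(floor(runif(n_total, -365, end_day)))]
  children[, sex := sample(c("female", "male"), n_total, replace = TRUE,
                           prob = c(0.491, 0.509))]
  restore()

  children <- clusters[, .(cluster_id, arm, region, csps_type,
                           true_rate)][children, on = "cluster_id"]

  # deaths
  restore <- local_rng(seeds[["deaths"]])
  hb <- rep(cfg$background_rate / 365.25, n_total)
  hc <- children$true_rate / 365.25
  age_death <- piecewise_age_at_death(n_total, hb, hc)
  # day-of-birth deaths recorded on day 1 of life; deaths after the study
  # horizon are unobservable and not part of the trial's truth
  dodv <- rep(NA_integer_, n_total)
  fin <- which(is.finite(age_death))
  dodv[fin] <- children$dob[fin] +
    pmax(1L, as.integer(floor(age_death[fin])))
  children[, dod := dodv]
  children[!is.na(dod) & dod > end_day, dod := NA_integer_]
  restore()

  # out-migration: geometric over census intervals, uniform day within
  restore <- local_rng(seeds[["migration"]])
  if (cfg$move_prob > 0 && cfg$n_rounds >= 1) {
    first_int <- rgeom(n_total, cfg$move_prob) + 1L   # 1-based interval
    day_in <- as.integer(floor(runif(n_total, 0, dl)))
    mv <- fifelse(first_int <= cfg$n_rounds,
                  census_dates[pmin(first_int, cfg$n_rounds)] + day_in,
                  NA_integer_)
    # a move before birth or after (observed) death never happens
    mv[!is.na(mv) & mv < children$dob] <- NA_integer_
    died_first <- !is.na(mv) & !is.na(children$dod) & children$dod <= mv
    mv[died_first] <- NA_integer_
    children[, moved_day := mv]
    # death after out-migration occurs elsewhere: not trial truth
    children[!is.na(moved_day) & !is.na(dod) & dod > moved_day,
             dod := NA_integer_]
  } else {
    children[, moved_day := NA_integer_]
  }
  restore()

  children[, true_rate := NULL]
  setcolorder(children, c("child_id", "cluster_id", "arm", "sex", "region",
                          "csps_type", "dob", "dod", "moved_day"))

  census <- derive_census_statuses(children, census_dates,
                                   unknown_prob = cfg$unknown_prob,
                                   seed = seeds[["census"]])

  mda <- CJ(cluster_id = clusters$cluster_id, round = seq_len(cfg$n_rounds))
  mda[, date := census_dates[round]]

  structure(list(children = children[], census = census,
                 census_dates = census_dates, mda = mda[],
                 clusters = clusters[], config = cfg),
            class = "trial_dataset")
}

#' Derive per-round census vital statuses from child dates
#'
#' Status at a census date is `dead` after the death day, `moved` after the
#' move day, `alive` otherwise; an alive child is misrecorded `unknown` with
#' probability `unknown_prob` (a missed household, independent across
#' rounds). Children born after a census date carry `NA` for that round
#' (not yet enumerated).
#'
#' @param children child table (`child_id`, `dob`, `dod`, `moved_day`).
#' @param census_dates increasing integer day indices.
#' @param unknown_prob per child-round probability of an `unknown` record.
#' @param seed RNG seed for the unknown-status noise.
#' @return long data.table: child_id, round, date, status.
#' @export
derive_census_statuses <- function(children, census_dates,
                                   unknown_prob = 0, seed = 1L) {
  if (is.unsorted(census_dates, strictly = TRUE))
    stop("census dates must be strictly increasing")
  grid <- CJ(child_id = children$child_id,
             round = seq_along(census_dates), sorted = FALSE)
  grid[, date := census_dates[round]]
  grid <- children[, .(child_id, dob, dod, moved_day)][grid, on = "child_id"]
  grid[, status := fcase(
    dob > date, NA_character_,
    !is.na(dod) & dod <= date, "dead",
    !is.na(moved_day) & moved_day <= date, "moved",
    default = "alive"
  )]
  if (unknown_prob > 0) {
    restore <- local_rng(seed)
    flip <- runif(nrow(grid)) < unknown_prob
    grid[flip & status == "alive", status := "unknown"]
    restore()
  }
  grid[, c("dob", "dod", "moved_day") := NULL]
  grid[]
}

#' Degrade a trial to a birth-history observation stream
#'
#' Emulates an endline birth-history interview: all live births in the 3-year
#' recall window before the final census are retained, and each true death is
#' reported with probability `sensitivity_bh`; a missed death appears as an
#' alive child. Movers are retained with their move day (their person-time is
#' censored at the move by the accrual step).
#'
#' @param trial a `trial_dataset` from [simulate_trial()].
#' @param sensitivity_bh reporting probability; defaults to the config value.
#' @param seed RNG seed; defaults to the degradation sub-stream.
#' @param recall_days recall window length before the final census (default
#'   3 x 365 days).
#' @return a child table like `trial$children` with under-reported deaths,
#'   with attribute `method = "birth_history"`.
#' @export
degrade_to_birth_history <- function(trial,
                                     sensitivity_bh = trial$config$sensitivity_bh,
                                     seed = NULL, recall_days = 3L * 365L) {
  stopifnot(inherits(trial, "trial_dataset"),
            sensitivity_bh >= 0, sensitivity_bh <= 1)
  if (is.null(seed)) seed <- component_seeds(trial$config$seed)[["degrade"]]
  end_day <- max(trial$census_dates)
  bh <- trial$children[dob >= end_day - recall_days & dob <= end_day]
  bh <- copy(bh)
  restore <- local_rng(seed)
  has_death <- !is.na(bh$dod)
  reported <- runif(nrow(bh)) < sensitivity_bh
  bh[has_death & !reported, dod := NA_integer_]
  restore()
  setattr(bh, "method", "birth_history")
  bh[]
}

#' Simulate verbal-autopsy style cause-of-death assignments
#'
#' Assigns each observed death in a trial a probable cause with a likelihood
#' score, in the style of an algorithmic verbal-autopsy coder: one primary
#' cause drawn from a common-cause distribution plus, for a fraction of
#' deaths, a lower-likelihood secondary cause. Used to exercise the
#' cause-specific analysis on synthetic data; real analyses ingest an
#' external coder's output instead.
#'
#' @param trial a `trial_dataset`.
#' @param causes character vector of cause labels.
#' @param probs cause distribution (recycled/normalised).
#' @param coverage fraction of deaths with a completed verbal autopsy.
#' @param seed RNG seed.
#' @return data.table: child_id, cluster_id, arm, cause, likelihood.
#' @export
simulate_cause_assignments <- function(trial,
                                       causes = c("acute respiratory infection",
                                                  "diarrhoeal disease",
                                                  "severe malnutrition",
                                                  "malaria", "sepsis",
                                                  "other"),
                                       probs = c(0.244, 0.225, 0.095, 0.15,
                                                 0.08, 0.206),
                                       coverage = 0.78, seed = 1L) {
  stopifnot(inherits(trial, "trial_dataset"))
  restore <- local_rng(seed)
  on.exit(restore())
  dead <- trial$children[!is.na(dod)]
  dead <- dead[runif(.N) < coverage]
  if (nrow(dead) == 0L) {
    return(data.table(child_id = character(), cluster_id = integer(),
                      arm = character(), cause = character(),
                      likelihood = numeric()))
  }
  probs <- probs / sum(probs)
  primary <- data.table(
    child_id = dead$child_id, cluster_id = dead$cluster_id, arm = dead$arm,
    cause = sample(causes, nrow(dead), replace = TRUE, prob = probs),
    likelihood = runif(nrow(dead), 0.4, 0.95)
  )
  # secondary, lower-likelihood causes for ~30% of deaths
  sec <- dead[runif(.N) < 0.3]
  secondary <- data.table(
    child_id = sec$child_id, cluster_id = sec$cluster_id, arm = sec$arm,
    cause = sample(causes, nrow(sec), replace = TRUE, prob = probs),
    likelihood = runif(nrow(sec), 0.05, 0.4)
  )
  rbind(primary, secondary)[]
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d clusters, %d children, %d rounds\n",
              nrow(x$clusters), nrow(x$children), x$config$n_rounds))
  tab <- x$clusters[, .N, by = arm]
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s=%d", tab$arm, tab$N), collapse = ", ")))
  cat(sprintf("  observed deaths (truth): %d\n", sum(!is.na(x$children$dod))))
  invisible(x)
}
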