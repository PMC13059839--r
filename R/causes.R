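#' Filter verbal-autopsy cause assignments
#'
#' Applies the trial's inclusion rules to externally assigned causes of
#' death: assignments with likelihood of 20% or less are dropped (strict
#' inequality — exactly 0.20 is excluded); when a child retains several
#' causes the highest-likelihood one is taken as the primary cause; and a
#' cause enters the comparison only if it is represented by more than 5
#' children overall with at least 1 child in each arm.
#'
#' @param assignments cause table: `child_id`, `cluster_id`, `arm`, `cause`,
#'   `likelihood` in \[0, 1\] (InterVA-style coder output).
#' @param likelihood_min likelihood threshold (strict), default 0.20.
#' @param min_total retained causes need total count > `min_total`
#'   (default 5).
#' @param min_per_arm minimum children per arm (default 1).
#' @return list: `primary` (one row per child with an above-threshold cause),
#'   `retained` (character vector of retained causes), `counts` (per-cause,
#'   per-arm counts).
#' @export
filter_causes <- function(assignments, likelihood_min = 0.20,
                          min_total = 5L, min_per_arm = 1L) {
  a <- as.data.table(assignments)
  need <- c("child_id", "cluster_id", "arm", "cause", "likelihood")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("cause table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(a$likelihood < 0 | a$likelihood > 1))
    stop("likelihood outside [0, 1]")

  a <- a[likelihood > likelihood_min]
  if (nrow(a) == 0L)
    return(list(primary = a, retained = character(0),
                counts = data.table(cause = character(), total = integer(),
                                    n_arms = integer())))
  setorder(a, child_id, -likelihood)
  primary <- a[, .SD[1L], by = child_id]

  counts <- primary[, .(total = .N, n_arms = uniqueN(arm),
                        min_arm = min(table(arm))), by = cause]
  retained <- counts[total > min_total & n_arms >= 2L &
                       min_arm >= min_per_arm, cause]
  list(primary = primary[], retained = sort(retained), counts = counts[])
}

#' Cause-specific incidence rate ratios with Bonferroni adjustment
#'
#' For each retained cause, fits the same cluster-level Poisson model as the
#' primary analysis with that cause's deaths as the outcome and the total
#' person-time as the offset (competing causes do not reduce the
#' denominator), then adjusts the Wald p-values for the number of causes
#' tested: p_adj = min(1, p x K).
#'
#' @param filtered output of [filter_causes()].
#' @param aggregates person-time aggregates (total person-years per cluster).
#' @param treated,control arm labels.
#' @return data.table: cause, deaths by arm, irr, ci_low, ci_high, p_wald,
#'   p_adjusted.
#' @export
cause_irrs <- function(filtered, aggregates, treated = "azithromycin",
                       control = "placebo") {
  agg <- per_cluster(check_aggregates(aggregates))
  primary <- as.data.table(filtered$primary)
  causes <- filtered$retained
  k <- length(causes)
  if (k == 0L)
    return(data.table(cause = character(), deaths_treated = integer(),
                      deaths_control = integer(), irr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_wald = numeric(), p_adjusted = numeric()))

  rows <- lapply(causes, function(cz) {
    dc <- primary[cause == cz, .(deaths = .N), by = cluster_id]
    a <- merge(agg[, .(cluster_id, arm, person_years)], dc,
               by = "cluster_id", all.x = TRUE)
    a[is.na(deaths), deaths := 0L]
    fit <- fit_irr(a, treated = treated, control = control)
    data.table(cause = cz,
               deaths_treated = as.integer(fit$deaths["treated"]),
               deaths_control = as.integer(fit$deaths["control"]),
               irr = fit$irr, ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_wald = fit$p_wald)
  })
  out <- rbindlist(rows)
  out[, p_adjusted := pmin(1, p_wald * k)]
  out[]
}
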