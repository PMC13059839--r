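#' Pooled mortality rate of one arm
#'
#' 1000 x (total deaths) / (total person-years) over the clusters of an arm.
#'
#' @param aggregates aggregate table (`cluster_id`, `arm`, `deaths`,
#'   `person_years`).
#' @param arm arm label to pool.
#' @return rate per 1000 person-years.
#' @export
pooled_rate <- function(aggregates, arm) {
  a <- as.data.frame(aggregates)
  sel <- a$arm == arm
  py <- sum(a$person_years[sel])
  if (py <= 0) stop("undefined rate: zero person-years in arm ", arm)
  1000 * sum(a$deaths[sel]) / py
}

check_aggregates <- function(aggregates) {
  a <- as.data.table(aggregates)
  need <- c("cluster_id", "arm", "deaths", "person_years")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("aggregate table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(a$deaths < 0) || any(a$person_years < 0))
    stop("negative deaths or person-years")
  a
}

# collapse to one row per cluster (aggregates may carry subgroup rows);
# keyed by cluster so resampling inference is invariant to input row order
per_cluster <- function(a) {
  a[, .(deaths = sum(deaths), person_years = sum(person_years)),
    keyby = .(cluster_id, arm)]
}

#' Incidence rate ratio from cluster-level Poisson regression
#'
#' Fits the trial's primary model: a Poisson regression with the number of
#' deaths per cluster as the outcome, treatment group as the only predictor
#' and log cluster person-time as an offset. The point estimate is
#' algebraically the ratio of the pooled arm rates; the 95% CI and Wald p
#' come from a sandwich (robust) variance clustered on the randomisation
#' unit. Clusters with zero person-time are excluded (and counted in the
#' result). An arm with zero deaths yields a degenerate IRR (0 or Inf) with
#' an undefined CI, reported as such rather than an error.
#'
#' @param aggregates aggregate table; one or more rows per cluster.
#' @param treated,control arm labels; the IRR is treated / control.
#' @param small_sample if `TRUE`, apply the G/(G-1) cluster correction to the
#'   sandwich variance (immaterial with hundreds of clusters; off by
#'   default).
#' @param conf_level confidence level, default 0.95.
#' @return an `irr_result` list: `irr`, `ci_low`, `ci_high`, `p_wald`,
#'   `log_irr`, `se_log_irr`, per-arm deaths / person-years / cluster
#'   counts, and `n_excluded` zero-person-time clusters.
#' @export
fit_irr <- function(aggregates, treated = "azithromycin",
                    control = "placebo", small_sample = FALSE,
                    conf_level = 0.95) {
  a <- per_cluster(check_aggregates(aggregates))
  a <- a[arm %in% c(treated, control)]
  n_excluded <- sum(a$person_years <= 0)
  if (n_excluded) {
    message(n_excluded, " cluster(s) with zero person-time excluded")
    a <- a[person_years > 0]
  }
  for (g in c(treated, control))
    if (nrow(a[arm == g]) < 1L) stop("no usable clusters in arm ", g)

  d_t <- sum(a[arm == treated, deaths]); py_t <- sum(a[arm == treated, person_years])
  d_c <- sum(a[arm == control, deaths]); py_c <- sum(a[arm == control, person_years])

  out <- list(
    irr = (d_t / py_t) / (d_c / py_c),
    deaths = c(treated = d_t, control = d_c),
    person_years = c(treated = py_t, control = py_c),
    n_clusters = c(treated = nrow(a[arm == treated]),
                   control = nrow(a[arm == control])),
    n_excluded = n_excluded, treated = treated, control = control
  )

  if (d_t == 0 || d_c == 0) {
    # degenerate-CI contract: no finite log-scale variance
    out$log_irr <- log(out$irr)
    out$se_log_irr <- NA_real_
    out$ci_low <- if (d_t == 0) 0 else NA_real_
    out$ci_high <- if (d_c == 0) Inf else NA_real_
    out$p_wald <- NA_real_
    class(out) <- "irr_result"
    return(out)
  }

  a[, trt := as.integer(arm == treated)]
  # quasipoisson: same point estimates as poisson, but tolerates the
  # fractional death counts produced by the misclassification correction;
  # the model-based dispersion is discarded in favour of the sandwich anyway
  fit <- glm(deaths ~ trt, family = stats::quasipoisson(),
             offset = log(person_years), data = a,
             control = list(epsilon = 1e-12, maxit = 200))
  vc <- sandwich::vcovCL(fit, cluster = a$cluster_id, cadjust = small_sample)
  b <- coef(fit)[["trt"]]
  se <- sqrt(vc["trt", "trt"])
  z <- qnorm(1 - (1 - conf_level) / 2)

  out$log_irr <- b
  out$se_log_irr <- se
  out$ci_low <- exp(b - z * se)
  out$ci_high <- exp(b + z * se)
  out$p_wald <- 2 * pnorm(-abs(b / se))
  class(out) <- "irr_result"
  out
}

#' @export
print.irr_result <- function(x, ...) {
  cat(sprintf("IRR (%s vs %s): %.3f (95%% CI %.3f to %.3f), Wald p = %.3g\n",
              x$treated, x$control, x$irr, x$ci_low, x$ci_high, x$p_wald))
  cat(sprintf("  %d / %.0f PY vs %d / %.0f PY over %d + %d clusters\n",
              x$deaths["treated"], x$person_years["treated"],
              x$deaths["control"], x$person_years["control"],
              x$n_clusters["treated"], x$n_clusters["control"]))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p = %.4f (%d replicates)\n",
                x$p_permutation, x$n_perm))
  invisible(x)
}

#' Incidence rate difference with cluster bootstrap CI
#'
#' Point estimate is the difference in pooled rates (treated minus control,
#' per 1000 person-years). The 95% CI comes from a non-parametric bootstrap
#' that resamples clusters with replacement; by default resampling is
#' stratified by arm, preserving the 2:1 design's per-arm cluster counts.
#' Replicates in which an arm ends up with zero person-time are redrawn and
#' counted.
#'
#' @param aggregates aggregate table.
#' @param n_boot bootstrap replicates, default 10000.
#' @param seed RNG seed.
#' @param treated,control arm labels.
#' @param stratified resample within arm (default) or across all clusters.
#' @param conf_level confidence level.
#' @return an `ird_result` list: `ird`, `ci_low`, `ci_high`, `n_boot`,
#'   `sd_boot` (bootstrap SD of the IRD, used by the bias analysis),
#'   `n_redrawn`, and the replicate vector `boot_ird`.
#' @export
bootstrap_ird <- function(aggregates, n_boot = 10000L, seed = 1L,
                          treated = "azithromycin", control = "placebo",
                          stratified = TRUE, conf_level = 0.95) {
  a <- per_cluster(check_aggregates(aggregates))
  a <- a[arm %in% c(treated, control) & person_years >= 0]
  restore <- local_rng(seed)
  on.exit(restore())

  d <- a$deaths; py <- a$person_years
  idx_t <- which(a$arm == treated); idx_c <- which(a$arm == control)
  rate <- function(i) 1000 * sum(d[i]) / sum(py[i])
  point <- rate(idx_t) - rate(idx_c)

  one_rep <- function() {
    if (stratified) {
      it <- sample(idx_t, length(idx_t), replace = TRUE)
      ic <- sample(idx_c, length(idx_c), replace = TRUE)
    } else {
      all_i <- sample(seq_len(nrow(a)), nrow(a), replace = TRUE)
      it <- all_i[a$arm[all_i] == treated]
      ic <- all_i[a$arm[all_i] == control]
    }
    if (sum(py[it]) <= 0 || sum(py[ic]) <= 0) return(NA_real_)
    rate(it) - rate(ic)
  }

  reps <- vapply(seq_len(n_boot), function(b) one_rep(), numeric(1))
  n_redrawn <- 0L
  while (anyNA(reps)) {
    bad <- which(is.na(reps))
    n_redrawn <- n_redrawn + length(bad)
    reps[bad] <- vapply(bad, function(b) one_rep(), numeric(1))
  }

  qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 names = FALSE)
  structure(list(ird = point, ci_low = qs[1], ci_high = qs[2],
                 n_boot = as.integer(n_boot), sd_boot = sd(reps),
                 n_redrawn = n_redrawn, boot_ird = reps,
                 treated = treated, control = control),
            class = "ird_result")
}

#' @export
print.ird_result <- function(x, ...) {
  cat(sprintf("IRD (%s - %s): %.3f per 1000 PY (95%% CI %.3f to %.3f)\n",
              x$treated, x$control, x$ird, x$ci_low, x$ci_high))
  cat(sprintf("  cluster bootstrap, %d replicates (%d redrawn)\n",
              x$n_boot, x$n_redrawn))
  invisible(x)
}

#' Monte Carlo permutation p-value for the rate ratio
#'
#' Re-randomises arm labels across clusters, preserving the observed per-arm
#' cluster counts (the 2:1 structure), and compares the observed
#' |log pooled-rate-ratio| with its permutation distribution. The reported
#' p-value uses the standard +1 Monte Carlo correction,
#' p = (1 + #\{T_perm >= T_obs\}) / (n_perm + 1). Replicates with zero deaths
#' in an arm have infinite |log ratio| and count as at least as extreme.
#' If no deaths occurred anywhere the statistic is degenerate and p = 1.
#'
#' @param aggregates aggregate table.
#' @param n_perm permutation replicates, default 10000.
#' @param seed RNG seed.
#' @param treated,control arm labels.
#' @return list: `p_permutation`, `statistic` (observed |log RR|), `n_perm`.
#' @export
permutation_p <- function(aggregates, n_perm = 10000L, seed = 1L,
                          treated = "azithromycin", control = "placebo") {
  a <- per_cluster(check_aggregates(aggregates))
  a <- a[arm %in% c(treated, control)]
  d <- a$deaths; py <- a$person_years
  n <- length(d); n_t <- sum(a$arm == treated)
  if (sum(d) == 0)
    return(list(p_permutation = 1, statistic = NA_real_,
                n_perm = as.integer(n_perm)))

  log_rr <- function(sel) {
    # sel: logical, TRUE = treated
    abs(log((sum(d[sel]) / sum(py[sel])) /
            (sum(d[!sel]) / sum(py[!sel]))))
  }
  t_obs <- log_rr(a$arm == treated)

  restore <- local_rng(seed)
  on.exit(restore())
  n_ge <- 0L
  block <- 2000L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    # b permuted 0/1 label vectors as an n x b matrix
    sel <- vapply(seq_len(b), function(i) {
      s <- logical(n); s[sample.int(n, n_t)] <- TRUE; s
    }, logical(n))
    dt <- colSums(d * sel); pyt <- colSums(py * sel)
    dc <- sum(d) - dt; pyc <- sum(py) - pyt
    t_perm <- abs(log((dt / pyt) / (dc / pyc)))  # Inf when dt or dc is 0
    t_perm[is.nan(t_perm)] <- Inf
    n_ge <- n_ge + sum(t_perm >= t_obs - 1e-12)
    done <- done + b
  }
  list(p_permutation = (1 + n_ge) / (n_perm + 1), statistic = t_obs,
       n_perm = as.integer(n_perm))
}

#' Full between-arm comparison of cluster aggregates
#'
#' Convenience wrapper running [fit_irr()], [bootstrap_ird()] and
#' [permutation_p()] on one aggregate table, mirroring how the primary and
#' secondary endpoints are analysed.
#'
#' @param aggregates aggregate table.
#' @param n_boot,n_perm replicate counts.
#' @param seed RNG seed (bootstrap uses `seed`, permutation `seed + 1`).
#' @param ... passed to [fit_irr()].
#' @return list with elements `irr` (`irr_result`, including the permutation
#'   p), `ird` (`ird_result`), and the pooled per-arm rates.
#' @export
compare_arms <- function(aggregates, n_boot = 10000L, n_perm = 10000L,
                         seed = 1L, ...) {
  irr <- fit_irr(aggregates, ...)
  perm <- permutation_p(aggregates, n_perm = n_perm, seed = seed + 1L,
                        treated = irr$treated, control = irr$control)
  irr$p_permutation <- perm$p_permutation
  irr$n_perm <- perm$n_perm
  ird <- bootstrap_ird(aggregates, n_boot = n_boot, seed = seed,
                       treated = irr$treated, control = irr$control)
  list(
    irr = irr, ird = ird,
    rate_treated = pooled_rate(aggregates, irr$treated),
    rate_control = pooled_rate(aggregates, irr$control)
  )
}
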