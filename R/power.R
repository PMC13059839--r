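#' Design parameters for a cluster-randomised rate comparison
#'
#' @param lambda0 control-arm rate per person-year.
#' @param relative_reduction assumed relative reduction (0.16 = 16%).
#' @param cv between-cluster coefficient of variation k of true rates.
#' @param clusters integer pair (treated, control) cluster counts.
#' @param py_per_cluster person-years of observation per cluster.
#' @param alpha two-sided significance level.
#' @param loss_to_followup fraction of clusters lost (applied to both arms).
#' @return a validated `design_params` list.
#' @export
design_params <- function(lambda0 = 0.01, relative_reduction = 0.16,
                          cv = 0.33, clusters = c(344L, 172L),
                          py_per_cluster = 327, alpha = 0.05,
                          loss_to_followup = 0) {
  p <- list(lambda0 = lambda0, relative_reduction = relative_reduction,
            cv = cv, clusters = as.numeric(clusters),
            py_per_cluster = py_per_cluster, alpha = alpha,
            loss_to_followup = loss_to_followup)
  if (p$lambda0 <= 0 || p$py_per_cluster <= 0) stop("rates and PY must be > 0")
  if (p$relative_reduction <= 0 || p$relative_reduction >= 1)
    stop("relative_reduction must be in (0, 1)")
  if (p$cv < 0) stop("cv must be >= 0")
  if (length(p$clusters) != 2L || any(p$clusters <= 0))
    stop("need positive cluster counts for both arms")
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must be in (0, 1)")
  if (p$loss_to_followup < 0 || p$loss_to_followup >= 1)
    stop("loss_to_followup must be in [0, 1)")
  class(p) <- "design_params"
  p
}

# Per-arm variance of a cluster-level rate estimate in the Hayes-Moulton
# framework: lambda/y within-cluster Poisson noise plus k^2 lambda^2
# between-cluster variation, divided by the number of clusters.
hm_arm_variance <- function(lambda, y, cv, c_arm, small_sample = FALSE) {
  denom <- if (small_sample) c_arm - 1 else c_arm
  (lambda / y + cv^2 * lambda^2) / denom
}

#' Power to detect a relative rate reduction in a cluster-randomised trial
#'
#' Normal-approximation power for the comparison of two incidence rates with
#' between-cluster variation, in the Hayes-Moulton form generalised to
#' unequal arm sizes: the difference lambda0 - lambda1 is tested against
#' standard error sqrt(sum over arms of (lambda_j/y + k^2 lambda_j^2)/c_j).
#'
#' @param p a [design_params()].
#' @param small_sample use c_j - 1 in place of c_j per arm (the conservative
#'   textbook variant); off by default, where several hundred clusters make
#'   it immaterial.
#' @return power (probability of two-sided rejection at `alpha`).
#' @export
power_for_effect <- function(p, small_sample = FALSE) {
  stopifnot(inherits(p, "design_params"))
  cl <- p$clusters * (1 - p$loss_to_followup)
  if (any(cl <= (if (small_sample) 1 else 0)))
    stop("zero effective clusters in an arm")
  l0 <- p$lambda0
  l1 <- l0 * (1 - p$relative_reduction)
  v <- hm_arm_variance(l1, p$py_per_cluster, p$cv, cl[1], small_sample) +
       hm_arm_variance(l0, p$py_per_cluster, p$cv, cl[2], small_sample)
  z_a <- qnorm(1 - p$alpha / 2)
  z <- (l0 - l1) / sqrt(v)
  pnorm(z - z_a) + pnorm(-z - z_a)
}

#' Smallest detectable relative reduction at a target power
#'
#' Numeric inversion of [power_for_effect()] over the relative reduction.
#'
#' @param p a [design_params()] (its `relative_reduction` is ignored).
#' @param target_power desired power in (0, 1).
#' @param small_sample see [power_for_effect()].
#' @return the relative reduction detectable with `target_power`.
#' @export
detectable_effect <- function(p, target_power = 0.8, small_sample = FALSE) {
  stopifnot(inherits(p, "design_params"),
            target_power > 0, target_power < 1)
  f <- function(r) {
    q <- p; q$relative_reduction <- r
    power_for_effect(q, small_sample) - target_power
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  if (f(hi) < 0)
    stop("target power unattainable even at a ", round(100 * hi),
         "% reduction; add clusters or person-time")
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Design effect of the cluster design
#'
#' Variance inflation of the cluster design relative to individual
#' randomisation for a rate with between-cluster coefficient of variation k:
#' 1 + k^2 lambda y, the ratio of cluster-level variance (lambda/y +
#' k^2 lambda^2) to its Poisson component. Reported as a diagnostic of the
#' design rather than a formula input.
#'
#' @param lambda rate per person-year.
#' @param py_per_cluster person-years per cluster.
#' @param cv coefficient of variation k.
#' @return the design effect.
#' @export
design_effect <- function(lambda, py_per_cluster, cv) {
  1 + cv^2 * lambda * py_per_cluster
}

#' Simulation-based power estimate at a design
#'
#' Empirical check of the analytic power: simulates cluster-level aggregates
#' at the design parameters (gamma-distributed true rates with the stated
#' cv, Poisson deaths over the per-cluster person-years), tests each trial
#' with the cluster-robust Poisson Wald test at `alpha`, and reports the
#' rejection fraction.
#'
#' @param p a [design_params()].
#' @param n_trials simulated trials.
#' @param seed RNG seed.
#' @return list: `power` (rejection fraction), `n_trials`, `mc_se`.
#' @export
simulate_power <- function(p, n_trials = 200L, seed = 1L) {
  stopifnot(inherits(p, "design_params"))
  restore <- local_rng(seed)
  on.exit(restore())
  cl <- round(p$clusters * (1 - p$loss_to_followup))
  arms <- rep(c("azithromycin", "placebo"), cl)
  means <- ifelse(arms == "azithromycin",
                  p$lambda0 * (1 - p$relative_reduction), p$lambda0)
  n <- length(arms)
  rej <- vapply(seq_len(n_trials), function(i) {
    rates <- if (p$cv == 0) means else {
      shape <- 1 / p$cv^2
      rgamma(n, shape = shape, scale = means / shape)
    }
    agg <- data.table(cluster_id = seq_len(n), arm = arms,
                      deaths = rpois(n, rates * p$py_per_cluster),
                      person_years = p$py_per_cluster)
    if (sum(agg$deaths[agg$arm == "azithromycin"]) == 0 ||
        sum(agg$deaths[agg$arm == "placebo"]) == 0) return(FALSE)
    fit <- fit_irr(agg)
    fit$p_wald < p$alpha
  }, logical(1))
  pw <- mean(rej)
  list(power = pw, n_trials = as.integer(n_trials),
       mc_se = sqrt(pw * (1 - pw) / n_trials))
}
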