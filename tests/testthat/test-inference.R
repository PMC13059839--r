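arm_totals_aggregates <- function(d_t, py_t, d_c, py_c) {
  data.table::data.table(
    cluster_id = 1:2, arm = c("azithromycin", "placebo"),
    deaths = c(d_t, d_c), person_years = c(py_t, py_c))
}

test_that("pooled rates per 1000 person-years", {
  a <- arm_totals_aggregates(397, 154051, 191, 77364)
  expect_equal(round(pooled_rate(a, "azithromycin"), 1), 2.6)
  expect_equal(round(pooled_rate(a, "placebo"), 1), 2.5)
  expect_equal(pooled_rate(arm_totals_aggregates(0, 500, 1, 1),
                           "azithromycin"), 0)
  expect_error(pooled_rate(arm_totals_aggregates(1, 0, 1, 1),
                           "azithromycin"), "zero person-years")
})

test_that("the offset-Poisson IRR equals the ratio of pooled rates", {
  set.seed(21)
  for (i in 1:5) {
    agg <- sim_cluster_aggregates(n_t = 14L, n_c = 7L, lambda0 = 0.02,
                                  irr = runif(1, 0.5, 1.5), py = 300)
    if (sum(agg$deaths[agg$arm == "placebo"]) == 0) next
    fit <- fit_irr(agg)
    ratio <- pooled_rate(agg, "azithromycin") / pooled_rate(agg, "placebo")
    # the glm coefficient itself, not just the reported ratio
    expect_equal(exp(fit$log_irr), ratio, tolerance = 1e-10)
    expect_equal(fit$irr, ratio, tolerance = 1e-12)
    expect_true(fit$ci_low <= fit$irr && fit$irr <= fit$ci_high)
    expect_true(fit$p_wald >= 0 && fit$p_wald <= 1)
  }
})

test_that("identical per-cluster data in both arms give IRR exactly 1", {
  a <- data.table::data.table(
    cluster_id = 1:6, arm = rep(c("azithromycin", "placebo"), each = 3),
    deaths = rep(c(2L, 5L, 3L), 2), person_years = rep(c(100, 200, 150), 2))
  expect_equal(fit_irr(a)$irr, 1, tolerance = 1e-12)
})

test_that("an arm with zero deaths yields the degenerate-CI contract", {
  a <- data.table::data.table(
    cluster_id = 1:4, arm = rep(c("azithromycin", "placebo"), each = 2),
    deaths = c(0L, 0L, 3L, 2L), person_years = rep(100, 4))
  fit <- fit_irr(a)
  expect_equal(fit$irr, 0)
  expect_equal(fit$ci_low, 0)
  expect_true(is.na(fit$p_wald))
})

test_that("zero person-time clusters are excluded and reported", {
  a <- data.table::data.table(
    cluster_id = 1:5, arm = c("azithromycin", "azithromycin", "placebo",
                              "placebo", "azithromycin"),
    deaths = c(3L, 2L, 4L, 1L, 2L), person_years = c(100, 120, 90, 80, 0))
  expect_message(fit <- fit_irr(a), "zero person-time")
  expect_equal(fit$n_excluded, 1L)
  expect_equal(unname(fit$deaths["treated"]), 5)
})

test_that("bootstrap IRD collapses when clusters are identical within arm", {
  a <- data.table::data.table(
    cluster_id = 1:9, arm = rep(c("azithromycin", "placebo"), c(6, 3)),
    deaths = rep(c(4L, 2L), c(6, 3)), person_years = rep(c(100, 100), c(6, 3)))
  b <- bootstrap_ird(a, n_boot = 200, seed = 1)
  expect_equal(b$ci_low, b$ird)
  expect_equal(b$ci_high, b$ird)
  expect_equal(b$ird, 1000 * (4 / 100 - 2 / 100))
})

test_that("bootstrap is reproducible and order-invariant under one seed", {
  set.seed(5)
  agg <- sim_cluster_aggregates(n_t = 20L, n_c = 10L)
  b1 <- bootstrap_ird(agg, n_boot = 500, seed = 42)
  b2 <- bootstrap_ird(agg, n_boot = 500, seed = 42)
  expect_identical(b1$ci_low, b2$ci_low)
  shuffled <- agg[sample(.N)]
  b3 <- bootstrap_ird(shuffled, n_boot = 500, seed = 42)
  expect_identical(b1$ci_low, b3$ci_low)
  expect_identical(b1$ird, b3$ird)
  p1 <- permutation_p(agg, n_perm = 500, seed = 42)
  p3 <- permutation_p(shuffled, n_perm = 500, seed = 42)
  expect_identical(p1$p_permutation, p3$p_permutation)
})

test_that("Monte Carlo permutation p matches exhaustive enumeration", {
  # 6 clusters, 4:2 allocation -> 15 possible label assignments
  a <- data.table::data.table(
    cluster_id = 1:6, arm = rep(c("azithromycin", "placebo"), c(4, 2)),
    deaths = c(5L, 1L, 3L, 7L, 2L, 1L),
    person_years = c(110, 95, 130, 160, 110, 100))
  d <- a$deaths; py <- a$person_years
  stat <- function(sel) abs(log((sum(d[sel]) / sum(py[sel])) /
                                (sum(d[!sel]) / sum(py[!sel]))))
  obs <- stat(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  combos <- utils::combn(6, 4)
  exact <- mean(apply(combos, 2, function(ix) {
    sel <- seq_len(6) %in% ix
    stat(sel) >= obs - 1e-12
  }))
  mc <- permutation_p(a, n_perm = 6000, seed = 3)
  expect_lt(abs(mc$p_permutation - exact), 0.02)
})

test_that("extreme separation drives the permutation p to its floor", {
  a <- data.table::data.table(
    cluster_id = 1:30, arm = rep(c("azithromycin", "placebo"), c(20, 10)),
    deaths = rep(c(10L, 0L), c(20, 10)), person_years = 100)
  p <- permutation_p(a, n_perm = 2000, seed = 1)
  expect_lt(p$p_permutation, 0.01)
  # degenerate: no deaths anywhere
  a0 <- data.table::copy(a)[, deaths := 0L]
  expect_equal(permutation_p(a0, n_perm = 100, seed = 1)$p_permutation, 1)
})

test_that("compare_arms bundles consistent IRR, IRD and permutation output", {
  set.seed(11)
  agg <- sim_cluster_aggregates(n_t = 20L, n_c = 10L, irr = 0.8)
  res <- compare_arms(agg, n_boot = 300, n_perm = 300, seed = 2)
  expect_equal(res$irr$irr, res$rate_treated / res$rate_control,
               tolerance = 1e-10)
  expect_equal(res$ird$ird, res$rate_treated - res$rate_control,
               tolerance = 1e-10)
  expect_true(res$irr$p_permutation > 0 && res$irr$p_permutation <= 1)
})
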