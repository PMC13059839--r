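test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(cv = -0.1), "cv")
  expect_error(sim_config(sensitivity_bh = 1.2), "sensitivity")
  expect_error(sim_config(baseline_rate = -1), "rates")
  expect_error(sim_config(allocation_ratio = c(2, 0)), "allocation")
})

test_that("configuration round-trips through YAML", {
  cfg <- sim_config(n_clusters = 30, seed = 42, effect_irr = 0.84)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  expect_equal(read_sim_config(path), cfg)
})

test_that("cv = 0 gives degenerate cluster rates at the arm means", {
  cfg <- sim_config(n_clusters = 30, cv = 0, effect_irr = 0.84, seed = 3)
  r <- draw_cluster_rates(cfg)
  arms <- attr(r, "arms")
  expect_equal(unname(r[arms == "placebo"]),
               rep(0.01, sum(arms == "placebo")))
  expect_equal(unname(r[arms == "azithromycin"]),
               rep(0.0084, sum(arms == "azithromycin")))
})

test_that("cluster rates match the configured cv and effect by moments", {
  cfg <- sim_config(n_clusters = 2000, cv = 0.33, effect_irr = 0.84,
                    seed = 7)
  r <- draw_cluster_rates(cfg)
  arms <- attr(r, "arms")
  for (g in c("azithromycin", "placebo")) {
    x <- r[arms == g]
    expect_gt(min(x), 0)
    expect_lt(abs(sd(x) / mean(x) - 0.33), 0.02)
  }
  expect_lt(abs(mean(r[arms == "azithromycin"]) /
                  mean(r[arms == "placebo"]) - 0.84), 0.05)
})

test_that("arm allocation respects the 2:1 ratio exactly", {
  cfg <- sim_config(n_clusters = 60, births_per_cluster_per_round = 5,
                    seed = 2)
  tr <- simulate_trial(cfg)
  expect_equal(sum(tr$clusters$arm == "azithromycin"), 40)
  expect_equal(sum(tr$clusters$arm == "placebo"), 20)
})

test_that("a trial with zero hazards and no movement has no events", {
  cfg <- sim_config(n_clusters = 12, baseline_rate = 0, background_rate = 0,
                    move_prob = 0, births_per_cluster_per_round = 15,
                    seed = 4)
  tr <- simulate_trial(cfg)
  expect_true(all(is.na(tr$children$dod)))
  expect_true(all(is.na(tr$children$moved_day)))
  bh <- degrade_to_birth_history(tr)
  expect_equal(sum(!is.na(bh$dod)), 0)
  agg <- accrue_census(tr$children, tr$census, clusters = tr$clusters)
  expect_equal(sum(agg$deaths), 0)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_clusters = 15, births_per_cluster_per_round = 10,
                    seed = 99)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$children, t2$children)
  expect_identical(t1$census, t2$census)
  expect_identical(degrade_to_birth_history(t1), degrade_to_birth_history(t2))
})

test_that("child records satisfy their structural invariants", {
  cfg <- sim_config(n_clusters = 25, births_per_cluster_per_round = 25,
                    seed = 12, baseline_rate = 0.05, background_rate = 0.08,
                    move_prob = 0.1)
  tr <- simulate_trial(cfg)
  ch <- tr$children
  expect_true(all(ch$dod > ch$dob, na.rm = TRUE))
  # death and move are never both terminal
  expect_equal(nrow(ch[!is.na(dod) & !is.na(moved_day) & moved_day < dod]), 0)
  # census statuses consistent with dates
  cs <- merge(tr$census, ch[, .(child_id, dob, dod, moved_day)],
              by = "child_id")
  expect_equal(nrow(cs[status == "dead" & (is.na(dod) | dod > date)]), 0)
  expect_equal(nrow(cs[status == "moved" &
                         (is.na(moved_day) | moved_day > date)]), 0)
  expect_equal(nrow(cs[!is.na(status) & dob > date]), 0)
})

test_that("census-enumerated rate recovers the configured truth", {
  cfg <- sim_config(n_clusters = 250, births_per_cluster_per_round = 60,
                    cv = 0, move_prob = 0, unknown_prob = 0, seed = 9)
  tr <- simulate_trial(cfg)
  agg <- accrue_census(tr$children, tr$census, clusters = tr$clusters)
  rate <- 1000 * sum(agg$deaths) / sum(agg$person_years)
  se <- 1000 * sqrt(sum(agg$deaths)) / sum(agg$person_years)
  expect_lt(abs(rate - 10), 3 * se)
})

test_that("birth-history degradation reports deaths binomially", {
  # fixed population with exactly 10,000 deaths
  n <- 12000L
  ch <- data.table::data.table(
    child_id = sprintf("d%05d", 1:n), cluster_id = 1L, arm = "azithromycin",
    sex = "female", region = "r", csps_type = "rural",
    dob = 0L, dod = c(rep(100L, 10000L), rep(NA_integer_, 2000L)),
    moved_day = NA_integer_)
  fake <- structure(list(children = ch, census_dates = c(0L, 182L, 364L),
                         config = sim_config(seed = 5L)),
                    class = "trial_dataset")
  exact <- degrade_to_birth_history(fake, sensitivity_bh = 1, seed = 8)
  expect_equal(sum(!is.na(exact$dod)), 10000L)
  none <- degrade_to_birth_history(fake, sensitivity_bh = 0, seed = 8)
  expect_equal(sum(!is.na(none$dod)), 0L)
  part <- degrade_to_birth_history(fake, sensitivity_bh = 0.8, seed = 8)
  k <- sum(!is.na(part$dod))
  expect_true(k >= qbinom(0.005, 10000, 0.8) &&
                k <= qbinom(0.995, 10000, 0.8))
  # monotone: same seed, higher sensitivity never reports fewer deaths
  ks <- sapply(c(0.2, 0.5, 0.8, 0.95), function(s)
    sum(!is.na(degrade_to_birth_history(fake, s, seed = 8)$dod)))
  expect_true(all(diff(ks) >= 0))
})
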