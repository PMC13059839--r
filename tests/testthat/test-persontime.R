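one_child <- function(dob = 0L, dod = NA_integer_, moved = NA_integer_,
                      cluster = 1L) {
  data.table::data.table(child_id = "k1", cluster_id = cluster,
                         arm = "azithromycin", dob = dob, dod = dod,
                         moved_day = moved)
}
mda1 <- data.frame(cluster_id = 1L, round = 1L, date = 200L)

test_that("the eligibility window is [dob + 30, dob + 365)", {
  expect_equal(unname(eligible_interval(0L)[1, ]), c(30L, 365L))
  expect_equal(unname(eligible_interval(100L)[1, ]), c(130L, 465L))
  expect_warning(eligible_interval(c(1L, NA)), "missing")
})

test_that("a fully eligible child accrues the whole MDA window", {
  agg <- accrue_birth_history(one_child(dob = 100L), mda1)
  expect_equal(agg$person_years, 182 / 365.25)
  expect_equal(agg$deaths, 0L)
})

test_that("death on the first eligible day of a window counts with zero time", {
  # dob 170: risk starts day 200 = window start; death that same day
  agg <- accrue_birth_history(one_child(dob = 170L, dod = 200L), mda1)
  expect_equal(agg$deaths, 1L)
  expect_equal(agg$person_years, 0)
  # a child dead before becoming eligible contributes nothing
  agg0 <- accrue_birth_history(one_child(dob = 190L, dod = 210L), mda1)
  expect_equal(agg0$deaths, 0L)
  expect_equal(agg0$person_years, 0)
})

test_that("birth-history person-time is censored at the terminal event", {
  agg_m <- accrue_birth_history(one_child(dob = 100L, moved = 250L), mda1)
  expect_equal(agg_m$person_years, 50 / 365.25)  # day 200 to move at 250
  agg_d <- accrue_birth_history(one_child(dob = 100L, dod = 250L), mda1)
  expect_equal(agg_d$person_years, 50 / 365.25)
  expect_equal(agg_d$deaths, 1L)
})

test_that("children in clusters without an MDA schedule are a hard error", {
  expect_error(accrue_birth_history(one_child(cluster = 9L), mda1),
               "no MDA schedule")
})

census_dates3 <- c(0L, 182L, 364L)

test_that("census intervals follow the half-time-for-deaths rule", {
  # alive -> alive, fully eligible (dob -100: risk [-70, 265))
  ch <- one_child(dob = -100L)
  agg <- accrue_census(ch, census_dates = census_dates3)
  # interval 1 fully eligible (182d), interval 2 eligible up to day 265
  expect_equal(agg$person_years, (182 + (265 - 182)) / 365.25)

  # alive -> dead: half the eligible intersection and one death
  chd <- one_child(dob = -100L, dod = 100L)
  aggd <- accrue_census(chd, census_dates = census_dates3)
  expect_equal(aggd$person_years, 182 / 2 / 365.25)
  expect_equal(aggd$deaths, 1L)

  # alive -> moved: nothing
  chm <- one_child(dob = -100L, moved = 100L)
  aggm <- accrue_census(chm, census_dates = census_dates3)
  expect_equal(aggm$person_years, 0)
  expect_equal(aggm$deaths, 0L)
})

test_that("census deaths outside the eligible age range are not counted", {
  # dies at age 20 days: never eligible, no death, but the alive->dead
  # interval still contributes (half of) zero eligible time
  ch <- one_child(dob = 50L, dod = 70L)
  agg <- accrue_census(ch, census_dates = census_dates3)
  expect_equal(agg$deaths, 0L)
  expect_equal(agg$person_years, 0)
})

test_that("non-monotone census dates are a hard error", {
  expect_error(accrue_census(one_child(), census_dates = c(0L, 182L, 100L)),
               "increasing")
  expect_error(accrue_census(one_child(), census_dates = 0L), "2 census")
})

test_that("both accrual procedures match the day-grid oracle", {
  for (seed in 1:4) {
    ch <- random_children(50L, n_clusters = 3L, seed = seed)
    mda <- data.table::CJ(cluster_id = 1:3, round = 1:2)
    mda[, date := c(0L, 182L)[round]]

    agg <- accrue_birth_history(ch, mda)
    orc <- oracle_birth_history(ch, mda)
    expect_equal(agg$deaths, orc$deaths)
    expect_equal(agg$person_years, orc$person_years, tolerance = 1e-12)

    cs <- derive_census_statuses(ch, census_dates3, unknown_prob = 0.1,
                                 seed = seed + 50L)
    agg2 <- accrue_census(ch, cs)
    orc2 <- oracle_census(ch, cs)
    expect_equal(agg2$deaths, orc2$deaths)
    expect_equal(agg2$person_years, orc2$person_years, tolerance = 1e-12)
  }
})

test_that("subgroup aggregates conserve the unsplit totals", {
  cfg <- sim_config(n_clusters = 20, births_per_cluster_per_round = 30,
                    baseline_rate = 0.05, move_prob = 0.1, seed = 31)
  tr <- simulate_trial(cfg)
  total <- accrue_birth_history(tr$children, tr$mda, clusters = tr$clusters)

  bands <- subgroup_split(tr$children, by = "age_band",
                          method = "birth_history", mda = tr$mda,
                          clusters = tr$clusters)
  bsum <- bands[, .(deaths = sum(deaths), person_years = sum(person_years)),
                keyby = cluster_id]
  expect_equal(bsum$deaths, total$deaths)
  expect_equal(bsum$person_years, total$person_years, tolerance = 1e-12)

  sexes <- subgroup_split(tr$children, by = "sex",
                          method = "birth_history", mda = tr$mda,
                          clusters = tr$clusters)
  ssum <- sexes[, .(deaths = sum(deaths), person_years = sum(person_years)),
                keyby = cluster_id]
  expect_equal(ssum$deaths, total$deaths)
  expect_equal(ssum$person_years, total$person_years, tolerance = 1e-12)

  # census-method age bands conserve too
  total_c <- accrue_census(tr$children, tr$census, clusters = tr$clusters)
  bands_c <- subgroup_split(tr$children, by = "age_band", method = "census",
                            census = tr$census, clusters = tr$clusters)
  bcsum <- bands_c[, .(deaths = sum(deaths),
                       person_years = sum(person_years)), keyby = cluster_id]
  expect_equal(bcsum$deaths, total_c$deaths)
  expect_equal(bcsum$person_years, total_c$person_years, tolerance = 1e-12)
})

test_that("a child seen only at young ages contributes nothing to 6-11m", {
  ch <- one_child(dob = 100L, dod = 250L)  # observed at ages 30-150 days
  bands <- subgroup_split(ch, by = "age_band", method = "birth_history",
                          mda = mda1)
  old <- bands[subgroup == "6-11 months"]
  expect_equal(old$deaths, 0L)
  expect_equal(old$person_years, 0)
})

test_that("age-band splits match the day-grid oracle", {
  ch <- random_children(40L, n_clusters = 2L, seed = 77)
  mda <- data.table::data.table(cluster_id = 1:2, round = 1L, date = 0L)
  bands <- subgroup_split(ch, by = "age_band", method = "birth_history",
                          mda = mda)
  orc_young <- oracle_birth_history(ch, mda, risk = c(30L, 183L))
  orc_old <- oracle_birth_history(ch, mda, risk = c(183L, 365L))
  expect_equal(bands[subgroup == "1-5 months", person_years],
               orc_young$person_years, tolerance = 1e-12)
  expect_equal(bands[subgroup == "6-11 months", deaths], orc_old$deaths)
})

test_that("extending a census interval never shrinks accrued person-time", {
  # for children under observation throughout (no terminal event), a longer
  # interval can only add eligible days
  ch <- random_children(60L, n_clusters = 2L, seed = 13)
  ch <- ch[is.na(dod) & is.na(moved_day)]
  short <- accrue_census(ch, census_dates = c(0L, 120L))
  long <- accrue_census(ch, census_dates = c(0L, 240L))
  expect_true(all(long$person_years >= short$person_years - 1e-12))
})
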