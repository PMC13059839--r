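# Brute-force day-grid oracles: walk every calendar day per child and tally
# eligibility, person-days and deaths. Deliberately independent of the
# package's interval arithmetic.

oracle_birth_history <- function(children, mda, window_days = 182L,
                                 risk = c(30L, 365L)) {
  ch <- as.data.frame(children)
  mda <- as.data.frame(mda)
  out <- list()
  for (cl in sort(unique(mda$cluster_id))) {
    dates <- mda$date[mda$cluster_id == cl]
    kids <- ch[ch$cluster_id == cl, , drop = FALSE]
    pt <- 0; dth <- 0
    for (i in seq_len(nrow(kids))) {
      k <- kids[i, ]
      term <- min(ifelse(is.na(k$dod), Inf, k$dod),
                  ifelse(is.na(k$moved_day), Inf, k$moved_day))
      for (m in dates) {
        for (t in m:(m + window_days - 1L)) {
          age <- t - k$dob
          if (age >= risk[1] && age < risk[2] && t >= k$dob && t < term)
            pt <- pt + 1
        }
        if (!is.na(k$dod)) {
          age_d <- k$dod - k$dob
          moved_first <- !is.na(k$moved_day) && k$moved_day <= k$dod
          if (age_d >= risk[1] && age_d < risk[2] &&
              k$dod >= m && k$dod < m + window_days && !moved_first)
            dth <- dth + 1
        }
      }
    }
    arm <- if (nrow(kids)) kids$arm[1] else NA_character_
    out[[length(out) + 1L]] <- data.frame(cluster_id = cl, arm = arm,
                                          deaths = dth,
                                          person_years = pt / 365.25)
  }
  do.call(rbind, out)
}

oracle_census <- function(children, census, risk = c(30L, 365L)) {
  ch <- as.data.frame(children)
  cs <- as.data.frame(census)
  dates <- unique(cs[order(cs$round), c("round", "date")])
  out <- list()
  for (cl in sort(unique(ch$cluster_id))) {
    kids <- ch[ch$cluster_id == cl, , drop = FALSE]
    pt <- 0; dth <- 0
    for (i in seq_len(nrow(kids))) {
      k <- kids[i, ]
      st <- cs[cs$child_id == k$child_id, ]
      st <- st[order(st$round), ]
      for (r in seq_len(nrow(dates) - 1L)) {
        s0 <- st$status[st$round == dates$round[r]]
        s1 <- st$status[st$round == dates$round[r + 1L]]
        if (length(s0) != 1L || length(s1) != 1L) next
        if (is.na(s0) || is.na(s1)) next
        if (s0 != "alive" || !(s1 %in% c("alive", "dead"))) next
        e <- 0
        for (t in dates$date[r]:(dates$date[r + 1L] - 1L)) {
          age <- t - k$dob
          if (age >= risk[1] && age < risk[2]) e <- e + 1
        }
        if (s1 == "dead") {
          pt <- pt + e / 2
          if (!is.na(k$dod)) {
            age_d <- k$dod - k$dob
            if (age_d >= risk[1] && age_d < risk[2]) dth <- dth + 1
          } else if (e > 0) dth <- dth + 1
        } else {
          pt <- pt + e
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      cluster_id = cl, arm = if (nrow(kids)) kids$arm[1] else NA_character_,
      deaths = dth, person_years = pt / 365.25)
  }
  do.call(rbind, out)
}

# random small child populations for oracle-equivalence checks
random_children <- function(n, n_clusters = 3L, end_day = 400L, seed = 1L) {
  set.seed(seed)
  dob <- sample(-365L:(end_day - 1L), n, replace = TRUE)
  age_death <- sample(c(rep(NA_integer_, n), sample(1L:500L, n, TRUE)), n)
  dod <- ifelse(is.na(age_death), NA_integer_, dob + age_death)
  moved <- ifelse(stats::runif(n) < 0.25,
                  dob + sample(1L:500L, n, TRUE), NA_integer_)
  # death and move: earlier event is terminal
  both <- !is.na(dod) & !is.na(moved)
  dod[both & moved < dod] <- NA_integer_
  moved[!is.na(dod) & both & dod <= moved] <- NA_integer_
  data.table::data.table(
    child_id = sprintf("k%04d", seq_len(n)),
    cluster_id = sample(seq_len(n_clusters), n, TRUE),
    arm = "azithromycin",
    sex = sample(c("female", "male"), n, TRUE),
    dob = as.integer(dob), dod = as.integer(dod),
    moved_day = as.integer(moved))
}

# cluster-level aggregate simulator: gamma cluster rates, Poisson deaths.
# Used by inference calibration tests; bypasses the child-level generator.
sim_cluster_aggregates <- function(n_t = 20L, n_c = 10L, lambda0 = 0.01,
                                   irr = 1, cv = 0.33, py = 327) {
  n <- n_t + n_c
  arms <- rep(c("azithromycin", "placebo"), c(n_t, n_c))
  m <- ifelse(arms == "azithromycin", lambda0 * irr, lambda0)
  rates <- if (cv == 0) m else {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, scale = m / shape)
  }
  data.table::data.table(
    cluster_id = seq_len(n), arm = arms,
    deaths = stats::rpois(n, rates * py), person_years = py)
}
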