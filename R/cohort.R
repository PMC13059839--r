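#' Default DHS-style infant age segments
#'
#' Completed-month segments 0, 1-2, 3-5 and 6-11 months, with day bounds
#' \[0,30), \[30,91), \[91,183), \[183,365).
#' @return data.table: label, seg_lo, seg_hi (half-open days of age).
#' @export
infant_age_segments <- function() {
  data.table(label = c("0", "1-2", "3-5", "6-11"),
             seg_lo = c(0L, 30L, 91L, 183L),
             seg_hi = c(30L, 91L, 183L, 365L))
}

#' Age-segment death probabilities for a synthetic cohort
#'
#' Computes, for each age segment, the probability of dying in the segment
#' conditional on reaching it, from births and deaths observed in a calendar
#' reference window — the synthetic-cohort device used by the Demographic and
#' Health Surveys. A child whose passage through a segment lies entirely
#' inside the window counts as one exposure; a cohort only partially exposed
#' (entering or leaving the segment outside the window) counts half. Deaths
#' are those at in-segment ages occurring inside the window. Children who die
#' before reaching a segment are not exposed to it.
#'
#' @param children birth records (`dob`, optional `dod`; day indices).
#' @param window length-2 calendar window `[start, end)` in day indices.
#' @param segments segment table as [infant_age_segments()].
#' @return data.table: label, seg_lo, seg_hi, deaths, exposures, q. Segments
#'   with zero exposure carry `q = NA` and raise a warning.
#' @export
segment_probabilities <- function(children, window,
                                  segments = infant_age_segments()) {
  ch <- as.data.table(children)
  stopifnot("dob" %in% names(ch), length(window) == 2L,
            window[2] > window[1])
  if (!"dod" %in% names(ch)) ch[, dod := NA_integer_]

  out <- copy(as.data.table(segments))
  out[, c("deaths", "exposures", "q") := {
    lo <- seg_lo; hi <- seg_hi
    enter <- ch$dob + lo; exit <- ch$dob + hi
    reached <- is.na(ch$dod) | ch$dod >= enter
    ol <- pmin(exit, window[2]) - pmax(enter, window[1])
    w <- fifelse(!reached | ol <= 0, 0,
                 fifelse(ol >= hi - lo, 1, 0.5))
    dth <- !is.na(ch$dod) & ch$dod >= enter & ch$dod < exit &
      ch$dod >= window[1] & ch$dod < window[2]
    list(sum(dth), sum(w), NA_real_)
  }, by = label]
  out[exposures > 0, q := deaths / exposures]
  if (any(out$exposures == 0))
    warning("segment(s) with zero exposure: q undefined")
  out[]
}

#' Cumulative mortality per 1000 live births
#'
#' Life-table combination of segment probabilities:
#' 1000 x (1 - prod(1 - q_j)).
#'
#' @param segments output of [segment_probabilities()] (or any table with a
#'   `q` column), or a bare numeric vector of probabilities.
#' @return deaths per 1000 live births.
#' @export
cumulative_mortality <- function(segments) {
  q <- if (is.numeric(segments)) segments else segments$q
  if (anyNA(q)) stop("undefined segment probability (zero exposure?)")
  if (any(q < 0 | q > 1)) stop("segment probabilities must lie in [0, 1]")
  1000 * (1 - prod(1 - q))
}

#' Per-arm synthetic-cohort mortality with cluster-bootstrap CI
#'
#' Runs the synthetic-cohort life table within each arm and, optionally,
#' attaches a percentile CI from resampling clusters with replacement
#' (the whole life-table computation is redone per replicate).
#'
#' @param children birth records with `cluster_id` and `arm`.
#' @param window calendar reference window `[start, end)`.
#' @param n_boot bootstrap replicates (0 to skip the CI).
#' @param seed RNG seed.
#' @param segments segment table.
#' @return data.table: arm, live_births, deaths, cum_mortality (per 1000
#'   live births), ci_low, ci_high.
#' @export
synthetic_cohort <- function(children, window, n_boot = 1000L, seed = 1L,
                             segments = infant_age_segments()) {
  ch <- as.data.table(children)
  stopifnot(all(c("cluster_id", "arm") %in% names(ch)))
  restore <- local_rng(seed)
  on.exit(restore())

  one_arm <- function(kids) {
    segs <- suppressWarnings(segment_probabilities(kids, window, segments))
    if (anyNA(segs$q)) return(NA_real_)
    cumulative_mortality(segs)
  }

  res <- lapply(sort(unique(ch$arm)), function(g) {
    kids <- ch[arm == g]
    est <- one_arm(kids)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0L) {
      cl <- unique(kids$cluster_id)
      by_cl <- split(seq_len(nrow(kids)), kids$cluster_id)
      reps <- vapply(seq_len(n_boot), function(b) {
        pick <- sample(cl, length(cl), replace = TRUE)
        one_arm(kids[unlist(by_cl[as.character(pick)], use.names = FALSE)])
      }, numeric(1))
      reps <- reps[!is.na(reps)]
      if (length(reps)) ci <- quantile(reps, c(0.025, 0.975), names = FALSE)
    }
    data.table(arm = g, live_births = nrow(kids),
               deaths = sum(!is.na(kids$dod)),
               cum_mortality = est, ci_low = ci[1], ci_high = ci[2])
  })
  rbindlist(res)
}
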