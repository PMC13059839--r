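#' Age-eligibility risk window of a child
#'
#' A child is eligible for MDA while aged 30-364 completed days; the risk
#' window is the half-open day interval `[dob + 30, dob + 365)`.
#'
#' @param dob integer day(s) of birth (day index from study start).
#' @return two-column matrix with columns `start`, `end`; rows with missing
#'   dob are `NA` and flagged with a warning (record skipped downstream).
#' @export
#' @examples
#' eligible_interval(0)    # 30 to 365
#' eligible_interval(100)  # 130 to 465
eligible_interval <- function(dob) {
  if (anyNA(dob)) warning("children with missing date of birth skipped")
  cbind(start = dob + 30L, end = dob + 365L)
}

DAYS_PER_YEAR <- 365.25

# pmin/pmax with NA meaning "no event"
event_or_inf <- function(x) fifelse(is.na(x), Inf, as.numeric(x))

check_children <- function(children) {
  need <- c("child_id", "cluster_id", "arm", "dob")
  miss <- setdiff(need, names(children))
  if (length(miss))
    stop("child table missing required column(s): ",
         paste(miss, collapse = ", "))
  ch <- as.data.table(children)
  if (!"dod" %in% names(ch)) ch[, dod := NA_integer_]
  if (!"moved_day" %in% names(ch)) ch[, moved_day := NA_integer_]
  if (anyNA(ch$dob)) {
    warning(sum(is.na(ch$dob)), " children with missing dob skipped")
    ch <- ch[!is.na(dob)]
  }
  bad <- ch[!is.na(dod) & dod <= dob]
  if (nrow(bad)) stop("date_of_death on or before date_of_birth for ",
                      nrow(bad), " children")
  ch
}

# Shared skeleton for per-cluster aggregation: sum contributions, keep every
# cluster in `cluster_frame` (zero-filled), attach arm labels.
aggregate_contributions <- function(contrib, cluster_frame, method,
                                    subgroup = NA_character_) {
  agg <- contrib[, .(deaths = sum(death), pt_days = sum(pt_days)),
                 by = cluster_id]
  out <- merge(cluster_frame, agg, by = "cluster_id", all.x = TRUE)
  out[is.na(deaths), deaths := 0L]
  out[is.na(pt_days), pt_days := 0]
  out[, `:=`(person_years = pt_days / DAYS_PER_YEAR, method = method,
             subgroup = subgroup)]
  out[, pt_days := NULL]
  setcolorder(out, c("cluster_id", "arm", "method", "subgroup", "deaths",
                     "person_years"))
  out[]
}

cluster_frame_from <- function(children, clusters, ids) {
  if (!is.null(clusters)) {
    cf <- as.data.table(clusters)[, .(cluster_id, arm)]
  } else {
    cf <- unique(as.data.table(children)[, .(cluster_id, arm)])
  }
  missing_ids <- setdiff(ids, cf$cluster_id)
  if (length(missing_ids))
    cf <- rbind(cf, data.table(cluster_id = missing_ids, arm = NA_character_))
  unique(cf, by = "cluster_id")
}

#' Accrue deaths and person-time from birth-history records
#'
#' Implements the birth-history enumeration rule: for each cluster and each
#' MDA round, deaths are those occurring within the 6-month (182-day) window
#' after the cluster's MDA among age-eligible children, and person-time is
#' the time a child was alive, age-eligible (30-364 days) and resident during
#' that window. Per child and round the contribution is the length of the
#' half-open intersection `risk window ∩ [mda, mda + window) ∩
#' [dob, terminal)`, where the terminal day is the earlier of death and
#' out-migration; the death is counted when the death day falls in
#' `risk ∩ window` and precedes any move. A death can therefore be
#' counted with zero accrued person-time (death on the first eligible day of
#' a window); rate models downstream handle such clusters explicitly.
#'
#' @param children child table (`child_id`, `cluster_id`, `arm`, `dob`,
#'   optional `dod`, `moved_day`; day indices).
#' @param mda MDA schedule: data.table/data.frame with `cluster_id`, `date`
#'   (one row per cluster-round).
#' @param window_days outcome window after each MDA round; default 182.
#' @param clusters optional cluster frame (`cluster_id`, `arm`) so clusters
#'   without children appear as zero rows.
#' @param risk_days age band accrued, default `c(30, 365)` (half-open days
#'   of age).
#' @return tidy aggregate data.table: cluster_id, arm, method, subgroup,
#'   deaths, person_years.
#' @export
accrue_birth_history <- function(children, mda, window_days = 182L,
                                 clusters = NULL, risk_days = c(30L, 365L)) {
  ch <- check_children(children)
  mda <- as.data.table(mda)
  stopifnot(all(c("cluster_id", "date") %in% names(mda)))
  unknown <- setdiff(unique(ch$cluster_id), unique(mda$cluster_id))
  if (length(unknown))
    stop("children reference cluster(s) with no MDA schedule: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  gap <- mda[order(date), if (.N > 1L) min(diff(date)) else NA_integer_,
             by = cluster_id]$V1
  if (any(gap < window_days, na.rm = TRUE))
    stop("MDA rounds closer than the outcome window would overlap")

  x <- merge(ch, mda[, .(cluster_id, mda_date = date)], by = "cluster_id",
             allow.cartesian = TRUE)
  x[, `:=`(risk_start = dob + risk_days[1], risk_end = dob + risk_days[2],
           terminal = pmin(event_or_inf(dod), event_or_inf(moved_day)),
           window_end = mda_date + window_days)]
  x[, pt_days := pmax(0, pmin(risk_end, window_end, terminal) -
                         pmax(risk_start, mda_date, dob))]
  x[, death := !is.na(dod) &
        dod >= pmax(risk_start, mda_date) &
        dod < pmin(risk_end, window_end) &
        (is.na(moved_day) | moved_day > dod)]

  cf <- cluster_frame_from(ch, clusters, mda$cluster_id)
  aggregate_contributions(x, cf, method = "birth_history")
}

#' Accrue deaths and person-time from census rounds
#'
#' Implements the inter-census enumeration rule: within each interval between
#' consecutive censuses, a child recorded alive at both ends contributes the
#' length of `risk window ∩ interval`; a child alive at the start and
#' dead at the next census contributes half of that intersection and one
#' death; a child recorded moved or unknown at the next census contributes
#' no person-time and no death for that interval. A death is counted only
#' when the age at death lies inside the eligibility band (out-of-age-range
#' deaths are excluded, as a verbal-autopsy review would do); when the death
#' day is unavailable the death is attributed whenever the child was
#' age-eligible at some point in the interval.
#'
#' @param children child table as in [accrue_birth_history()].
#' @param census either a long status table (`child_id`, `round`, `date`,
#'   `status` in alive/dead/moved/unknown) or `NULL` to derive statuses from
#'   the child dates via [derive_census_statuses()].
#' @param census_dates increasing day indices of the census rounds (required
#'   when `census` is `NULL`; otherwise taken from the table).
#' @param clusters optional cluster frame for zero-filled clusters.
#' @param risk_days age band accrued, default `c(30, 365)`.
#' @return tidy aggregate data.table as in [accrue_birth_history()].
#' @export
accrue_census <- function(children, census = NULL, census_dates = NULL,
                          clusters = NULL, risk_days = c(30L, 365L)) {
  ch <- check_children(children)
  if (is.null(census)) {
    if (is.null(census_dates)) stop("need census dates or a status table")
    census <- derive_census_statuses(ch, census_dates)
  }
  census <- as.data.table(census)
  stopifnot(all(c("child_id", "round", "date", "status") %in% names(census)))
  dates <- unique(census[order(round), .(round, date)])
  if (nrow(dates) < 2L) stop("need at least 2 census rounds")
  if (is.unsorted(dates$date, strictly = TRUE))
    stop("census dates must be strictly increasing")

  # pair consecutive rounds: status at interval start and end
  s <- dcast(census, child_id ~ round, value.var = "status")
  rounds <- dates$round
  pieces <- vector("list", nrow(dates) - 1L)
  for (k in seq_len(nrow(dates) - 1L)) {
    r0 <- as.character(rounds[k]); r1 <- as.character(rounds[k + 1L])
    pieces[[k]] <- data.table(
      child_id = s$child_id,
      status_start = s[[r0]], status_end = s[[r1]],
      interval_start = dates$date[k], interval_end = dates$date[k + 1L]
    )
  }
  x <- rbindlist(pieces)
  x <- x[status_start == "alive" & status_end %in% c("alive", "dead")]
  x <- merge(x, ch, by = "child_id")

  x[, `:=`(risk_start = dob + risk_days[1], risk_end = dob + risk_days[2])]
  x[, pt_days := pmax(0, pmin(risk_end, interval_end) -
                         pmax(risk_start, interval_start))]
  x[status_end == "dead", pt_days := pt_days / 2]
  x[, death := status_end == "dead" &
        fifelse(!is.na(dod), dod >= risk_start & dod < risk_end,
                pt_days > 0)]

  cf <- cluster_frame_from(ch, clusters, unique(ch$cluster_id))
  aggregate_contributions(x, cf, method = "census")
}

#' Subgroup accrual
#'
#' Re-runs an enumeration procedure within subgroups. Sex, region and CSPS
#' type partition children whole; the age-band split (1-5 vs 6-11 completed
#' months) partitions each child's person-time at the day the child turns 6
#' completed months (day 183 from birth), so band aggregates sum exactly to
#' the unsplit aggregates.
#'
#' @param children child table.
#' @param by one of `"age_band"`, `"sex"`, `"region"`, `"csps_type"`.
#' @param method `"birth_history"` or `"census"`.
#' @param mda MDA schedule (birth-history method).
#' @param census,census_dates census inputs (census method).
#' @param clusters optional cluster frame.
#' @param window_days birth-history outcome window.
#' @return stacked aggregates with the `subgroup` column set to the level.
#' @export
subgroup_split <- function(children, by = c("age_band", "sex", "region",
                                            "csps_type"),
                           method = c("birth_history", "census"),
                           mda = NULL, census = NULL, census_dates = NULL,
                           clusters = NULL, window_days = 182L) {
  by <- match.arg(by)
  method <- match.arg(method)
  ch <- as.data.table(children)

  accrue_one <- function(kids, risk, label) {
    agg <- if (method == "birth_history") {
      accrue_birth_history(kids, mda, window_days = window_days,
                           clusters = clusters, risk_days = risk)
    } else {
      accrue_census(kids, census, census_dates, clusters = clusters,
                    risk_days = risk)
    }
    agg[, subgroup := label][]
  }

  if (by == "age_band") {
    rbind(accrue_one(ch, c(30L, 183L), "1-5 months"),
          accrue_one(ch, c(183L, 365L), "6-11 months"))
  } else {
    if (!by %in% names(ch))
      stop("grouping column not present on child records: ", by)
    levels <- sort(unique(ch[[by]]))
    if (anyNA(ch[[by]])) stop("unknown (missing) level in grouping field ", by)
    rbindlist(lapply(levels, function(lv)
      accrue_one(ch[get(by) == lv], c(30L, 365L), lv)))
  }
}
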