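#!/usr/bin/env Rscript
# Stage 2 — enumerate deaths and person-years at risk, both ways.
#
# Birth history: deaths within 182 days of each cluster's MDA among
# age-eligible (30-364 day old) children, person-time while alive, eligible
# and resident in those windows. Census: inter-census intervals, half
# person-time for children who die, none for movers/unknowns.

suppressPackageStartupMessages({library(crtmort); library(data.table)})

children <- read_children_csv("scratch/trial/children.csv")
bh_children <- read_children_csv("scratch/trial/birth_history_children.csv")
mda <- read_schedule_csv("scratch/trial/mda_schedule.csv")
census <- fread("scratch/trial/census_status.csv")
clusters <- fread("scratch/trial/clusters.csv")

agg_bh <- accrue_birth_history(bh_children, mda, clusters = clusters)
agg_cs <- accrue_census(children, census, clusters = clusters)
aggregates <- rbind(agg_bh, agg_cs)
write_table_csv(aggregates, "results/aggregates.csv")

for (m in c("birth_history", "census")) {
  a <- aggregates[method == m]
  cat(sprintf("%-13s deaths %4d + %3d | person-years %8.0f + %7.0f | rates %.2f / %.2f per 1000 PY\n",
              m,
              a[arm == "azithromycin", sum(deaths)],
              a[arm == "placebo", sum(deaths)],
              a[arm == "azithromycin", sum(person_years)],
              a[arm == "placebo", sum(person_years)],
              pooled_rate(a, "azithromycin"), pooled_rate(a, "placebo")))
}

# subgroup accrual (age band, sex, region, CSPS type) for the birth history
subs <- rbindlist(lapply(c("age_band", "sex", "region", "csps_type"),
                         function(b) subgroup_split(bh_children, by = b,
                                                    method = "birth_history",
                                                    mda = mda,
                                                    clusters = clusters)))
write_table_csv(subs, "scratch/aggregates_subgroups.csv")
cat("wrote results/aggregates.csv and scratch/aggregates_subgroups.csv\n")
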