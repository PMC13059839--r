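#!/usr/bin/env Rscript
# Stage 7 — cause-specific mortality comparison.
#
# Consumes verbal-autopsy style cause assignments (here simulated on top of
# the trial's deaths; a real analysis would ingest an external coder's CSV),
# applies the inclusion filters (>20% likelihood, primary cause per child,
# >5 children overall and >=1 per arm), and fits the per-cause cluster
# Poisson models with Bonferroni-adjusted p values.

suppressPackageStartupMessages({library(crtmort); library(data.table)})

cfg <- read_sim_config("scratch/trial/sim_config.yaml")
trial <- simulate_trial(cfg)   # same seed -> same trial as stage 1
va <- simulate_cause_assignments(trial, coverage = 0.78, seed = 20260929L)
cat(sprintf("verbal autopsies: %d assignments on %d children (%.0f%% of %d deaths)\n",
            nrow(va), length(unique(va$child_id)),
            100 * length(unique(va$child_id)) / sum(!is.na(trial$children$dod)),
            sum(!is.na(trial$children$dod))))

flt <- filter_causes(va)
cat("retained causes:", paste(flt$retained, collapse = ", "), "\n\n")

aggregates <- fread("results/aggregates.csv")
res <- cause_irrs(flt, aggregates[method == "birth_history"])
print(res)

write_table_csv(res, "results/causes.csv")
cat("\nwrote results/causes.csv\n")
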