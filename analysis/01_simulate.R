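#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic trial.
#
# One complete cluster-randomised MDA trial at the study conditions:
# 516 clusters randomised 2:1, a control-arm rate of 10 deaths per 1000
# person-years among 30-364 day olds with between-cluster cv 0.33, four
# biannual MDA rounds, and a null true effect (IRR 1), matching what the
# trial itself estimated. The census stream and the (degraded) birth-history
# stream both derive from this one truth.

suppressPackageStartupMessages(library(crtmort))

cfg <- sim_config(seed = 20260929L)   # all defaults = study conditions
print(cfg)

trial <- simulate_trial(cfg)
print(trial)

paths <- export_trial(trial, "scratch/trial")
bh <- degrade_to_birth_history(trial)
write_table_csv(bh, "scratch/trial/birth_history_children.csv")

cat(sprintf("birth-history stream: %d children, %d reported deaths (of %d true among them)\n",
            nrow(bh), sum(!is.na(bh$dod)),
            sum(!is.na(trial$children[trial$children$child_id %in% bh$child_id]$dod))))
cat("wrote:", paste(basename(paths), collapse = ", "),
    "and birth_history_children.csv under scratch/trial/\n")
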