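n_clusters: 24
allocation_ratio:
- 2
- 1
baseline_rate: 0.01
effect_irr: 1.0
cv: 0.33
births_per_cluster_per_round: 25
n_rounds: 4
round_interval_days: 182
sensitivity_bh: 0.85
move_prob: 0.05
background_rate: 0.03
unknown_prob: 0.02
seed: 2026
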