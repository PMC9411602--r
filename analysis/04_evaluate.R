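#!/usr/bin/env Rscript
# Stage 4 — prevalence-adjusted, horizon and stratified evaluation.
#
# Scores the held-out test records: at the time of diagnosis (records with
# a visit within 3 months of T0), across early-detection horizons (CKD
# records truncated h years before T0; healthy records untruncated), and
# stratified by life stage and by pre-T0 visit count. PPV/NPV use the
# population prevalence 0.83%, not the sample mix.

suppressPackageStartupMessages(library(ckdwatch))

catalog <- default_catalog()
net <- load_net("results/model.json")
test <- read_labeled_cohort("results/test_imputed_ehr.csv",
                            "results/test_labels.csv", catalog)

prev <- default_prevalence()
t0_summary <- evaluate_at_t0(net, test, prevalence = prev)
readr::write_csv(t0_summary, "results/t0_summary.csv", na = "")
cat(sprintf(
  "at T0 (n=%d CKD, %d no-CKD): sensitivity %.1f%% [%.1f, %.1f], specificity %.1f%%, PPV %.1f%%, NPV %.2f%%\n",
  t0_summary$n_pos, t0_summary$n_neg,
  100 * t0_summary$sensitivity, 100 * t0_summary$sens_lower,
  100 * t0_summary$sens_upper, 100 * t0_summary$specificity,
  100 * t0_summary$ppv, 100 * t0_summary$npv))

horizon <- horizon_evaluation(net, test, prevalence = prev)
readr::write_csv(horizon, "results/horizon_table.csv", na = "")
cat("early-detection sensitivity by horizon (years before diagnosis):\n")
for (i in seq_len(nrow(horizon))) {
  cat(sprintf("  %.1f y: %5.1f%%  (n=%d)\n", horizon$horizon_years[i],
              100 * horizon$sensitivity[i], horizon$n_pos[i]))
}

by_stage <- stratified_report(net, test, "life-stage", prevalence = prev)
readr::write_csv(by_stage, "results/by_life_stage.csv", na = "")
by_visits <- stratified_report(net, test, "visit-count", prevalence = prev)
readr::write_csv(by_visits, "results/by_visit_count.csv", na = "")
cat("wrote t0_summary, horizon_table, by_life_stage, by_visit_count under results/\n")
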