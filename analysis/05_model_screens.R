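#!/usr/bin/env Rscript
# Stage 5 (desk scale) — wrapper feature selection and architecture screen.
#
# Reruns the model-building searches at a size a workstation handles in
# minutes: greedy forward/backward wrapper selection with the 3-7 selection
# net over a compact candidate panel, and a reduced architecture grid
# scored by cross-validated F1. The production defaults (6 features,
# 5-3-3) are what these searches are screening over.

suppressPackageStartupMessages(library(ckdwatch))

SEED <- 42
catalog <- default_catalog()
train <- read_labeled_cohort("results/train_imputed_ehr.csv",
                             "results/train_labels.csv", catalog)
# a compact status-balanced subsample keeps every retrain inside a
# desk-scale budget
st <- vapply(train, function(r) r$status, character(1))
keep <- withr::with_seed(SEED, {
  c(sample(which(st == "CKD"), min(60, sum(st == "CKD"))),
    sample(which(st == "NO_CKD"), min(60, sum(st == "NO_CKD"))))
})
train <- train[sort(keep)]

sel <- wrapper_feature_selection(
  c("creatinine", "BUN", "USG", "age"), train,
  base_config = net_config(hidden_layers = c(3, 7), dropout = 0,
                           epochs = 3, seed = stage_seed(SEED, 5)),
  folds = 3)
readr::write_csv(sel$forward, "results/feature_selection_forward.csv")
readr::write_csv(sel$backward, "results/feature_selection_backward.csv")
cat("forward selection order:\n")
print(sel$forward)

scaler <- fit_feature_scaler(train)
samples <- build_sequences(augment_truncations(train), scaler)
grid <- list(
  net_config(hidden_layers = c(5, 3, 3), epochs = 3,
             seed = stage_seed(SEED, 6)),
  net_config(hidden_layers = c(10), epochs = 3,
             seed = stage_seed(SEED, 6)),
  net_config(hidden_layers = c(20, 20), epochs = 3,
             seed = stage_seed(SEED, 6))
)
screen <- architecture_screen(grid, samples, scaler, folds = 3)
readr::write_csv(screen$table, "results/architecture_screen.csv")
cat("architecture screen (mean CV F1):\n")
print(screen$table)
cat(sprintf("selected architecture: %s\n",
            paste(screen$best$hidden_layers, collapse = "-")))
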