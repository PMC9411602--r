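#!/usr/bin/env Rscript
# Stage 2 — rule-based CKD status assignment and cohort filtering.
#
# Labels every record (CKD via diagnosis code with T0 at the first
# diagnosed visit; PROBABLE_CKD via risk tokens or >= 2 CKD-suggesting
# criteria; NO_CKD when >= 2 disease-free years validate the label), masks
# extreme lab outliers, drops lab-free pre-T0 visits, and keeps records
# with adequate pre-T0 blood and urine coverage. Probable records are
# labeled and counted but never modeled.

suppressPackageStartupMessages(library(ckdwatch))

catalog <- default_catalog()
records <- read_ehr_table("results/ehr_cohort.csv", catalog)

labeled <- label_cohort(records, catalog)
statuses <- vapply(labeled, function(r) r$status, character(1))
cat("status counts:", paste(names(table(statuses)), table(statuses),
                            sep = "=", collapse = ", "), "\n")

modelable <- labeled[statuses %in% c("CKD", "NO_CKD")]
summary_tab <- summarize_cohort(modelable)
readr::write_csv(summary_tab, "results/cohort_summary.csv", na = "")
cat(sprintf("at T0: CKD creatinine %.2f (%.2f) vs no-CKD %.2f (%.2f) mg/dL\n",
            summary_tab$mean_creatinine_t0[summary_tab$status == "CKD"],
            summary_tab$sd_creatinine_t0[summary_tab$status == "CKD"],
            summary_tab$mean_creatinine_t0[summary_tab$status == "NO_CKD"],
            summary_tab$sd_creatinine_t0[summary_tab$status == "NO_CKD"]))

sds <- population_sds(modelable, catalog)
masked <- mask_outliers(modelable, catalog, sds)
cat(sprintf("masked %d extreme outlier value(s)\n", attr(masked, "n_masked")))
trimmed <- lapply(masked, drop_lab_free_visits, catalog = catalog)

filt <- filter_eligible(trimmed, catalog)
cat(sprintf("eligibility: kept %d, rejected %d\n",
            length(filt$kept), nrow(filt$rejected)))
readr::write_csv(filt$rejected, "results/rejections.csv", na = "")

# persist the eligible cohort (usable visits only) plus its labels
eligible_records <- lapply(filt$kept, function(r) {
  patient_record(r$patient$patient_id, r$patient$sex, r$patient$breed,
                 r$usable_visits)
})
write_ehr_table(eligible_records, "results/eligible_ehr.csv")
write_labels(filt$kept, "results/labels.csv")

funnel <- data.frame(
  stage = c("simulated", "labeled_ckd", "labeled_nockd", "labeled_probable",
            "excluded", "eligible", "rejected"),
  n = c(length(records), sum(statuses == "CKD"), sum(statuses == "NO_CKD"),
        sum(statuses == "PROBABLE_CKD"), sum(statuses == "EXCLUDED"),
        length(filt$kept), nrow(filt$rejected))
)
readr::write_csv(funnel, "results/funnel.csv")
cat("wrote results/eligible_ehr.csv, labels.csv, cohort_summary.csv, funnel.csv\n")
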