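#!/usr/bin/env Rscript
# Longitudinal exposure models: cubic-spline smooths over days of
# azithromycin exposure (basis 4, first 10 hospital days, first 5
# exposure days) with co-antibiotic smooths, covariates and a patient
# random intercept; LRT for the azithromycin term. Also the persistence
# comparison: MLS richness 7-10 days after azithromycin cessation vs the
# late exposure window.

library(azresistome)
suppressMessages(library(dplyr))

out <- "results/longitudinal"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata("results/data/sample_metadata.csv")
taxa <- readr::read_tsv("results/filtered/taxa_filtered.tsv", show_col_types = FALSE)
args <- readr::read_tsv("results/filtered/args_filtered.tsv", show_col_types = FALSE)
intervals <- readr::read_csv("results/data/antibiotic_intervals.csv",
                             show_col_types = FALSE)
design <- readr::read_csv("results/single_timepoint/analysis_design.csv",
                          show_col_types = FALSE)

clin <- meta[!meta$is_negative_control, ]
patients <- readr::read_csv("results/data/patients.csv", show_col_types = FALSE)
metrics <- sample_metrics(taxa, args, clin$sample_id) |>
  left_join(exposure_day_counts(clin, intervals), by = "sample_id") |>
  left_join(patients[, c("patient_id", "age_quintile", "sex",
                         "trajectory_group", "steroids_ever")],
            by = "patient_id")
co_cols <- setdiff(grep("_days$", names(metrics), value = TRUE), "azithro_days")

for (resp in c("mls_richness", "mls_proportion")) {
  dat <- metrics[!is.na(metrics[[resp]]), ]
  fit <- suppressWarnings(fit_exposure_trend(
    dat, resp, co_drugs = co_cols,
    covariates = c("trajectory_group", "sex", "age_quintile", "steroids_ever")))
  readr::write_csv(fit$curve, file.path(out, paste0("trend_", resp, ".csv")))
  message(sprintf("%s ~ s(azithro days): LRT p = %.3g, day-0 to day-5 change = %+.3f (n = %d)",
                  resp, fit$lrt_p,
                  fit$curve$fit[nrow(fit$curve)] - fit$curve$fit[1], fit$n_used))
}

# persistence: samples 7-10 d after the last azithromycin day
exposures <- expand_exposures(intervals)
az_pat <- exposures$patient_id[vapply(exposures$azithro_days, length, 1L) > 0]
persist_ids <- unlist(lapply(az_pat, function(p) {
  cess <- max(exposures$azithro_days[[match(p, exposures$patient_id)]])
  s <- clin[clin$patient_id == p, ]
  s$sample_id[persistence_window(s$day_from_admission, cess)]
}))
late_ids <- design$sample_id[design$included & design$window == "late" &
                               design$group == "Azithro"]
a <- metrics$mls_richness[metrics$sample_id %in% persist_ids]
b <- metrics$mls_richness[metrics$sample_id %in% late_ids]
if (length(a) >= 3 && length(b) >= 3) {
  pt <- pairwise_rank_test(a, b)
  message(sprintf(
    "persistence: MLS richness %.2f (post-cessation, n=%d) vs %.2f (late window, n=%d), rank-sum p = %.3g",
    mean(a), length(a), mean(b), length(b), pt$p_value))
  readr::write_csv(tibble::tibble(
    comparison = "post_cessation_vs_late_window",
    mean_post_cessation = mean(a), n_post = length(a),
    mean_late_window = mean(b), n_late = length(b), p = pt$p_value
  ), file.path(out, "persistence.csv"))
} else {
  message("persistence window too sparse at this cohort size; no test run")
}
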