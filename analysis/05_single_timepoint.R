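#!/usr/bin/env Rscript
# Single-timepoint contrasts: assign exposure groups, pick the early
# (1 +/- 1 d of exposure) and late (5 +/- 1 d) windows with matched,
# 50%-rarefied No-Abx controls, then compare metrics between groups with
# a site-random-intercept linear mixed model plus pairwise rank-sum tests
# and fold changes; BH across each metric family.

library(azresistome)
suppressMessages(library(dplyr))

out <- "results/single_timepoint"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- as.integer(sub("seed: ", "", readLines("results/data/config.txt")[1]))

meta <- read_sample_metadata("results/data/sample_metadata.csv")
taxa <- readr::read_tsv("results/filtered/taxa_filtered.tsv", show_col_types = FALSE)
args <- readr::read_tsv("results/filtered/args_filtered.tsv", show_col_types = FALSE)
intervals <- readr::read_csv("results/data/antibiotic_intervals.csv",
                             show_col_types = FALSE)

clin <- meta[!meta$is_negative_control, ]
exposures <- assign_exposure_group(complete_exposures(
  expand_exposures(intervals), clin$patient_id))
design <- build_analysis_design(clin, exposures, seed = seed)
readr::write_csv(design, file.path(out, "analysis_design.csv"))

patients <- readr::read_csv("results/data/patients.csv", show_col_types = FALSE)
metrics <- sample_metrics(taxa, args, clin$sample_id) |>
  left_join(exposure_day_counts(clin, intervals), by = "sample_id") |>
  left_join(design[, c("sample_id", "group", "window", "included")],
            by = "sample_id") |>
  left_join(patients[, c("patient_id", "age_quintile", "sex",
                         "trajectory_group", "steroids_ever")],
            by = "patient_id")
co_cols <- grep("_days$", names(metrics), value = TRUE)
co_cols <- setdiff(co_cols, "azithro_days")
resp <- c("mls_richness", "total_bacterial_rpm", "shannon_taxa")

rows <- list()
for (w in c("early", "late")) {
  dat <- metrics[metrics$included & metrics$window == w, ]
  for (r in resp) {
    dd <- dat[!is.na(dat[[r]]), ]
    if (length(unique(dd$group)) < 2) next
    fit <- fit_group_model(
      dd, r,
      covariates = c("age_quintile", "sex", "trajectory_group",
                     "day_from_admission", "steroids_ever", co_cols),
      random = "site_id")
    rows[[length(rows) + 1]] <- tibble::tibble(
      window = w, metric = r, term = fit$term, estimate = fit$estimate,
      se = fit$se, p = fit$p
    )
    # pairwise rank tests + fold changes vs the No-Abx reference
    for (g in setdiff(unique(dd$group), "No-Abx")) {
      a <- dd[[r]][dd$group == g]
      b <- dd[[r]][dd$group == "No-Abx"]
      fc <- tryCatch(fold_change(a, b), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        window = w, metric = r, term = paste0("ranksum_", g, "_vs_NoAbx"),
        estimate = fc, se = NA_real_,
        p = pairwise_rank_test(a, b)$p_value
      )
    }
  }
}
res <- bind_rows(rows) |>
  group_by(window, grepl("^ranksum", term)) |>
  mutate(q = bh_adjust(p)) |>
  ungroup() |>
  select(window, metric, term, estimate, se, p, q)
readr::write_csv(res, file.path(out, "group_contrasts.csv"))

message("group contrasts (mixed model + rank tests), BH-adjusted per window/family:")
sig <- res[res$q < 0.05, ]
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %s %-20s %-28s est %6.2f  q = %.3g",
                  sig$window[i], sig$metric[i], sig$term[i],
                  sig$estimate[i], sig$q[i]))
}
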