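test_that("generation is deterministic given the seed and sensitive to it", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg, seed = 5)
  b <- simulate_dataset(cfg, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_identical(a$taxa, b$taxa)
  expect_identical(a$args, b$args)
  c_ <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(a$taxa, c_$taxa))
})

test_that("degenerate group probabilities are honoured and validated", {
  cfg <- small_cfg(group_probabilities = c(Azithro = 1, `Other-Abx` = 0,
                                           `No-Abx` = 0))
  sim <- simulate_cohort(cfg, seed = 2)
  expect_true(all(sim$patients$plan_group == "Azithro"))
  expect_error(sim_config(group_probabilities = c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(sim_config(azithro_effect = 0), "azithro_effect")
})

test_that("empirical group fractions match the configured probabilities", {
  cfg <- sim_config(n_patients = 5000)
  sim <- simulate_cohort(cfg, seed = 10)
  frac <- table(sim$patients$plan_group) / 5000
  for (g in names(cfg$group_probabilities)) {
    expect_lt(abs(frac[[g]] - cfg$group_probabilities[[g]]), 0.02)
  }
})

test_that("azithromycin course length has the expected median and IQR shape", {
  cfg <- sim_config(n_patients = 3000)
  sim <- simulate_cohort(cfg, seed = 4)
  az <- sim$intervals[sim$intervals$antibiotic == "azithromycin", ]
  dur <- az$stop_day - az$start_day + 1
  expect_equal(median(dur), 2)
  expect_lte(quantile(dur, 0.25), 2)
  expect_gte(quantile(dur, 0.75), 3)
  expect_true(all(dur >= 1 & dur <= 35))
})

test_that("negative controls carry contamination only", {
  sim <- simulate_dataset(small_cfg(), seed = 7)
  ctl_ids <- sim$samples$sample_id[sim$samples$is_negative_control]
  expect_length(ctl_ids, small_cfg()$n_negative_controls)
  ctl_taxa <- sim$taxa[sim$taxa$sample_id %in% ctl_ids, ]
  expect_true(all(ctl_taxa$name %in% sim$truth$contaminant_taxa))
  ctl_args <- sim$args[sim$args$sample_id %in% ctl_ids, ]
  expect_true(all(ctl_args$gene %in% sim$truth$contaminant_genes))
})

test_that("control means converge to the batch contamination profile", {
  cfg <- small_cfg(n_negative_controls = 400)
  sim <- simulate_dataset(cfg, seed = 3)
  ctl <- sim$samples[sim$samples$is_negative_control, ]
  rec <- sim$taxa[sim$taxa$sample_id %in% ctl$sample_id, ]
  tab <- pivot_to_table(rec, "name", "reads", "reads")
  # zero-fill controls with no record at all of some contaminant
  batch <- ctl$batch[match(rownames(tab), ctl$sample_id)]
  for (b in unique(batch)) {
    est <- colMeans(unclass(tab)[batch == b, , drop = FALSE])
    truth <- sim$truth$mu_taxa[b, colnames(tab)]
    # relative error shrinks with n_controls; 100 controls/batch here
    expect_lt(median(abs(est - truth) / pmax(truth, 1)), 0.25)
  }
})

test_that("the exposure effect is confined to MLS-class genes", {
  cfg <- sim_config(n_patients = 250, azithro_effect = 2,
                    qc_fail_rate = 0, sample_dropout = 0)
  sim <- simulate_dataset(cfg, seed = 21)
  meta <- sim$samples
  args <- add_abundance(sim$args, meta)
  args <- args[!grepl("contamARG", args$gene), ]
  ex <- complete_exposures(expand_exposures(sim$intervals),
                           sim$patients$patient_id)
  clin <- meta[!meta$is_negative_control, ]
  az_days <- ex$azithro_days[match(clin$patient_id, ex$patient_id)]
  cum <- mapply(function(d, day) sum(d <= day), az_days, clin$day_from_admission)
  exposed <- clin$sample_id[cum >= 3]
  unexposed <- clin$sample_id[cum == 0]
  mls_mean <- function(ids, cls) {
    sub <- args[args$sample_id %in% ids &
                  (args$drug_class == "MLS") == cls, ]
    mean(sub$dpm)
  }
  # strong inflation in MLS, none in other classes
  expect_gt(mls_mean(exposed, TRUE) / mls_mean(unexposed, TRUE), 2)
  expect_lt(abs(log(mls_mean(exposed, FALSE) / mls_mean(unexposed, FALSE))), 0.35)
})

test_that("a null effect leaves MLS expression exchangeable between groups", {
  cfg <- sim_config(n_patients = 150, azithro_effect = 1, qc_fail_rate = 0)
  sim <- simulate_dataset(cfg, seed = 31)
  args <- add_abundance(sim$args, sim$samples)
  mls <- args[args$drug_class == "MLS", ]
  per_sample <- tapply(mls$dpm, mls$sample_id, sum)
  groups <- sim$patients$plan_group[match(
    sim$samples$patient_id[match(names(per_sample), sim$samples$sample_id)],
    sim$patients$patient_id)]
  p <- pairwise_rank_test(per_sample[groups == "Azithro"],
                          per_sample[groups == "No-Abx"])$p_value
  expect_gt(p, 0.01)
})

test_that("generated fixtures survive the report writers, readers and full chain", {
  sim <- simulate_dataset(small_cfg(), seed = 13)
  dir <- withr::local_tempdir()
  tpath <- file.path(dir, "taxa.tsv")
  apath <- file.path(dir, "args.tsv")
  mpath <- file.path(dir, "meta.csv")
  write_taxon_report(sim$taxa, tpath)
  write_arg_report(sim$args, apath)
  readr::write_csv(sim$samples, mpath)
  taxa <- read_taxon_report(tpath)
  args <- read_arg_report(apath)
  meta <- read_sample_metadata(mpath)
  expect_equal(nrow(taxa), nrow(sim$taxa))
  expect_equal(nrow(args), nrow(sim$args))

  dec <- decontaminate_records(taxa, meta, "name")
  filt <- filter_taxa(dec$records)
  expect_gt(nrow(filt$retained), 0)
  dec_a <- decontaminate_records(args, meta, "gene")
  args_dpm <- add_abundance(dec_a$records, meta)
  surv <- filter_args(args_dpm, arg_prevalence(args_dpm))
  expect_gt(nrow(surv$retained), 0)
})
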