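#' Complete an exposure table to a full patient roster
#'
#' Patients without any recorded antibiotic interval (the No-Abx group)
#' get empty day sets and `complete_dates = TRUE` so group assignment can
#' treat the roster as a partition.
#'
#' @param exposures Output of [expand_exposures()].
#' @param patient_ids Full roster of patient ids.
#' @return Exposure tibble covering every patient.
#' @export
complete_exposures <- function(exposures, patient_ids) {
  missing <- setdiff(patient_ids, exposures$patient_id)
  if (length(missing) == 0) return(exposures)
  filler <- tibble::tibble(
    patient_id = missing,
    azithro_days = replicate(length(missing), integer(0), simplify = FALSE),
    other_abx_days = replicate(length(missing), integer(0), simplify = FALSE),
    complete_dates = TRUE
  )
  dplyr::bind_rows(exposures, filler)
}

#' Cumulative per-drug exposure days at each sample's collection
#'
#' For every sample, counts the days of each tracked antibiotic given up
#' to and including the collection day — the per-drug day counts entering
#' the statistical models as fixed effects or smooth terms.
#'
#' @param samples Sample metadata (`sample_id`, `patient_id`,
#'   `day_from_admission`).
#' @param intervals Exposure interval table.
#' @param drugs Drugs to track (default azithromycin plus the six common
#'   co-antibiotics).
#' @return `samples` with one cumulative day-count column per drug
#'   (syntactic names: `azithro_days`, `ceftriaxone_days`, ...).
#' @export
exposure_day_counts <- function(samples, intervals,
                                drugs = c("azithromycin", TRACKED_CO_DRUGS)) {
  col_of <- function(drug) {
    if (drug == "azithromycin") "azithro_days" else
      paste0(gsub("[^a-z]", "_", drug), "_days")
  }
  day_sets <- lapply(drugs, function(drug) {
    iv <- intervals[intervals$antibiotic == drug, , drop = FALSE]
    split_days <- lapply(split(iv, iv$patient_id), function(df) {
      sort(unique(unlist(Map(seq, df$start_day, df$stop_day))))
    })
    split_days
  })
  names(day_sets) <- drugs
  for (drug in drugs) {
    ds <- day_sets[[drug]]
    samples[[col_of(drug)]] <- vapply(seq_len(nrow(samples)), function(i) {
      set <- ds[[samples$patient_id[i]]]
      if (is.null(set)) 0L else sum(set <= samples$day_from_admission[i])
    }, integer(1))
  }
  samples
}

#' Decontaminate long report records against batch-matched controls
#'
#' Pivots the records to a counts table, fits the negative-binomial null
#' on the negative-control rows, applies [apply_decontam()] to the
#' clinical rows, and filters the long records to the retained pairs.
#' Taxa and resistance genes are decontaminated as two separate runs.
#'
#' @param records Taxon or ARG record tibble including control samples.
#' @param meta Sample metadata with `sample_id`, `batch`,
#'   `is_negative_control`.
#' @param feature_col `"name"` for taxa, `"gene"` for ARGs.
#' @param fdr,family Passed to [apply_decontam()].
#' @return List: `records` (retained clinical records), `decisions`,
#'   `null`.
#' @export
decontaminate_records <- function(records, meta, feature_col,
                                  fdr = 0.1, family = "per-sample") {
  tab <- pivot_to_table(records, feature_col, "reads", "reads")
  meta_idx <- match(rownames(tab), meta$sample_id)
  if (anyNA(meta_idx)) {
    stop("sample(s) missing from metadata: ",
         paste(rownames(tab)[is.na(meta_idx)], collapse = ", "), call. = FALSE)
  }
  is_ctl <- meta$is_negative_control[meta_idx]
  ctl_tab <- unclass(tab)[is_ctl, , drop = FALSE]
  clin_tab <- feature_table(unclass(tab)[!is_ctl, , drop = FALSE],
                            value_kind(tab))
  null <- fit_null(ctl_tab, meta$batch[meta_idx][is_ctl])
  res <- apply_decontam(clin_tab, meta$batch[meta_idx][!is_ctl], null,
                        fdr = fdr, family = family)
  retained_key <- paste(res$decisions$sample_id[res$decisions$retained],
                        res$decisions$feature[res$decisions$retained],
                        sep = "\r")
  rec_key <- paste(records$sample_id, records[[feature_col]], sep = "\r")
  keep <- rec_key %in% retained_key
  list(records = records[keep, , drop = FALSE],
       decisions = res$decisions, null = null, table = res$table)
}

#' Per-sample microbiome and resistome metrics
#'
#' @param taxa Filtered taxon records with an `rpm` column.
#' @param args Filtered ARG records with a `dpm` column.
#' @param sample_ids Sample universe (samples with no surviving records
#'   get zero totals and `NA` diversity).
#' @return Tibble: `sample_id`, `total_bacterial_rpm`, `total_fungal_rpm`,
#'   `shannon_taxa`, `shannon_args`, `mls_richness`, `total_dpm`,
#'   `mls_proportion`.
#' @export
sample_metrics <- function(taxa, args, sample_ids) {
  bact <- taxa[taxa$kingdom == "bacteria", ]
  fung <- taxa[taxa$kingdom == "fungi", ]
  agg <- function(df, val) {
    out <- tapply(df[[val]], df$sample_id, sum)
    v <- rep(0, length(sample_ids)); names(v) <- sample_ids
    v[names(out)] <- out
    v
  }
  shan <- function(df, val) {
    vapply(sample_ids, function(s) {
      x <- df[[val]][df$sample_id == s]
      if (length(x) == 0 || sum(x) == 0) NA_real_ else shannon(x)
    }, numeric(1))
  }
  prof <- resistome_profiles(args, sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    total_bacterial_rpm = unname(agg(bact, "rpm")),
    total_fungal_rpm = unname(agg(fung, "rpm")),
    shannon_taxa = unname(shan(bact, "rpm")),
    shannon_args = unname(shan(args, "dpm")),
    mls_richness = prof$mls_richness,
    total_dpm = prof$total_dpm,
    mls_proportion = prof$mls_proportion
  )
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' simulate -> decontaminate (taxa and genes separately) -> quality-filter
#' -> normalise -> design -> per-sample metrics -> group comparisons and
#' the longitudinal exposure trend for MLS richness.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed covering generation, design rarefaction and
#'   any downstream resampling.
#' @param fdr Decontamination retention threshold.
#' @return List: `data` (the generated dataset), `taxa`, `args` (filtered,
#'   normalised records), `design`, `metrics` (per-sample metric table
#'   joined with design and covariates), `group_results` (early/late MLS
#'   richness contrasts), `trend` (smooth exposure model for MLS
#'   richness).
#' @export
run_pipeline <- function(cfg = sim_config(), seed = 1, fdr = 0.1) {
  data <- simulate_dataset(cfg, seed = seed)
  meta <- validate_sample_metadata(data$samples)
  clin_meta <- meta[!meta$is_negative_control, ]

  dec_taxa <- decontaminate_records(data$taxa, meta, "name", fdr = fdr)
  dec_args <- decontaminate_records(data$args, meta, "gene", fdr = fdr)

  taxa_f <- filter_taxa(dec_taxa$records)$retained
  args_dpm <- add_abundance(dec_args$records, meta)
  prev <- arg_prevalence(args_dpm)
  args_f <- filter_args(args_dpm, prev)$retained
  taxa_f <- add_abundance(taxa_f, meta)

  exposures <- complete_exposures(expand_exposures(data$intervals),
                                  data$patients$patient_id)
  exposures <- assign_exposure_group(exposures)
  design <- build_analysis_design(clin_meta, exposures, seed = seed)

  metrics <- sample_metrics(taxa_f, args_f, clin_meta$sample_id)
  covar <- exposure_day_counts(clin_meta, data$intervals)
  covar <- dplyr::left_join(covar, data$patients[, c(
    "patient_id", "age_quintile", "sex", "trajectory_group", "steroids_ever"
  )], by = "patient_id")
  metrics <- dplyr::left_join(metrics, covar, by = "sample_id")
  metrics <- dplyr::left_join(
    metrics,
    design[, c("sample_id", "group", "window", "included", "reassigned")],
    by = "sample_id"
  )

  co_cols <- paste0(gsub("[^a-z]", "_", TRACKED_CO_DRUGS), "_days")
  group_results <- lapply(c(early = "early", late = "late"), function(w) {
    dat <- metrics[metrics$included & metrics$window == w &
                     !is.na(metrics$mls_richness), ]
    if (length(unique(dat$group)) < 2 || nrow(dat) < 20) return(NULL)
    fit_group_model(
      dat, "mls_richness",
      covariates = c("age_quintile", "sex", "trajectory_group",
                     "day_from_admission", "steroids_ever", co_cols),
      random = "site_id"
    )
  })

  trend_dat <- metrics[!is.na(metrics$mls_richness), ]
  trend <- fit_exposure_trend(
    trend_dat, "mls_richness", co_drugs = co_cols,
    covariates = c("trajectory_group", "sex", "age_quintile", "steroids_ever")
  )

  list(data = data, taxa = taxa_f, args = args_f, design = design,
       metrics = metrics, group_results = group_results, trend = trend)
}
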