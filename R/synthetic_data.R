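#' Default resistance-gene catalogue for the generator
#'
#' Fixed gene -> drug-class table with approximate gene lengths (bases).
#' The MLS block carries the erm/msr/mph/mef genes observed in upper-airway
#' resistomes; the remaining classes provide the non-MLS background whose
#' expression should not respond to azithromycin.
#'
#' @return Tibble: `gene`, `drug_class`, `gene_length`.
#' @export
default_gene_classes <- function() {
  tibble::tribble(
    ~gene, ~drug_class, ~gene_length,
    "ermA",  "MLS", 732,
    "ermB",  "MLS", 738,
    "ermC",  "MLS", 735,
    "msrA",  "MLS", 1467,
    "mphC",  "MLS", 906,
    "mefA",  "MLS", 1218,
    "lnuA",  "MLS", 486,
    "vgaA",  "MLS", 1569,
    "tetM",  "tetracycline", 1920,
    "tetW",  "tetracycline", 1920,
    "tetL",  "tetracycline", 1377,
    "blaZ",  "beta-lactam", 846,
    "blaTEM", "beta-lactam", 861,
    "mecA",  "beta-lactam", 2007,
    "aph3-IIIa", "aminoglycoside", 795,
    "aadE",  "aminoglycoside", 909,
    "vanA",  "glycopeptide", 1032,
    "sul1",  "sulfonamide", 840,
    "dfrG",  "trimethoprim", 498,
    "qnrB",  "fluoroquinolone", 681
  )
}

default_genera <- function() {
  bacteria <- c(
    "Staphylococcus", "Corynebacterium", "Dolosigranulum", "Moraxella",
    "Streptococcus", "Haemophilus", "Neisseria", "Fusobacterium",
    "Klebsiella", "Prevotella", "Veillonella", "Rothia", "Gemella",
    "Actinomyces", "Lawsonella", "Cutibacterium", "Pseudomonas",
    "Enterobacter", "Acinetobacter", "Lactobacillus", "Porphyromonas",
    "Leptotrichia", "Granulicatella", "Abiotrophia", "Micrococcus",
    "Anaerococcus", "Finegoldia", "Peptoniphilus", "Campylobacter",
    "Capnocytophaga", "Selenomonas", "Eikenella", "Aggregatibacter",
    "Bergeyella", "Alloprevotella", "Tannerella", "Treponema",
    "Parvimonas", "Dialister", "Atopobium"
  )
  fungi <- c("Candida", "Malassezia", "Aspergillus", "Cladosporium",
             "Penicillium", "Saccharomyces")
  tibble::tibble(
    name = c(bacteria, fungi),
    kingdom = rep(c("bacteria", "fungi"), c(length(bacteria), length(fungi)))
  )
}

default_contaminant_taxa <- function() {
  # Water/reagent-associated genera typical of sequencing background.
  c("Ralstonia", "Bradyrhizobium", "Sphingomonas", "Burkholderia",
    "Methylobacterium", "Delftia", "Stenotrophomonas", "Cupriavidus",
    "Pelomonas", "Herbaspirillum", "Acidovorax", "Aquabacterium",
    "Phyllobacterium", "Mesorhizobium", "Novosphingobium", "Caulobacter",
    "Brevundimonas", "Variovorax", "Comamonas", "Undibacterium",
    "Janthinobacterium", "Massilia", "Duganella", "Roseomonas",
    "Paucibacter", "Limnobacter", "Polaromonas", "Hydrogenophaga",
    "Rhodoferax", "Curvibacter")
}

#' Simulation configuration
#'
#' Defaults encode the cohort conditions the pipeline targets: 1,164
#' patients across 15 sites and 4 sequencing batches, 26 water controls,
#' nasal sampling at admission and days 4/7/14/21/28, roughly 2 million
#' post-host microbial reads per sample, group frequencies 31.4% / 27.8% /
#' 40.7% (azithromycin / other antibiotics / none), azithromycin courses
#' with median 2 days (IQR 1-4), and ceftriaxone then vancomycin as the
#' commonest co-prescriptions. `azithro_effect` is the multiplicative
#' per-exposure-day inflation applied to latent MLS gene expression (1 =
#' no effect).
#'
#' @param n_patients,n_sites,n_negative_controls Cohort dimensions.
#' @param batches Sequencing batch labels.
#' @param sampling_days Scheduled collection days from admission.
#' @param sample_dropout Probability a scheduled follow-up visit is missed
#'   (the admission sample is always collected).
#' @param total_reads_mean,total_reads_cv Per-sample microbial read total
#'   (lognormal mean and coefficient of variation).
#' @param group_probabilities Named probabilities for Azithro, Other-Abx
#'   and No-Abx patients; must sum to 1.
#' @param incomplete_dates_rate Fraction of treated patients whose
#'   antibiotic dates are only partially captured (excluded downstream).
#' @param azithro_effect Per-exposure-day multiplicative effect on latent
#'   MLS DPM (> 0).
#' @param contamination_theta NB dispersion of the contamination
#'   background; `n_contaminant_taxa`/`n_contaminant_genes` set the size of
#'   the contaminant feature panels.
#' @param ar1_rho Within-patient AR(1) correlation of log-abundances
#'   across visits.
#' @param qc_fail_rate Fraction of emitted records deliberately corrupted
#'   to fail each quality-control rule.
#' @param gene_classes Gene -> class table (see [default_gene_classes()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1164,
                       n_sites = 15,
                       batches = c("1", "2", "3A", "3B"),
                       n_negative_controls = 26,
                       sampling_days = c(0, 4, 7, 14, 21, 28),
                       sample_dropout = 0.15,
                       total_reads_mean = 2e6,
                       total_reads_cv = 0.05,
                       group_probabilities = c(Azithro = 366 / 1164,
                                               `Other-Abx` = 324 / 1164,
                                               `No-Abx` = 474 / 1164),
                       incomplete_dates_rate = 0.02,
                       azithro_effect = 1.5,
                       contamination_theta = 2,
                       n_contaminant_taxa = 30,
                       n_contaminant_genes = 4,
                       ar1_rho = 0.6,
                       qc_fail_rate = 0.05,
                       gene_classes = default_gene_classes()) {
  if (abs(sum(group_probabilities) - 1) > 1e-8) {
    stop("group probabilities must sum to 1", call. = FALSE)
  }
  if (any(group_probabilities < 0)) stop("negative group probability", call. = FALSE)
  if (azithro_effect <= 0) stop("azithro_effect must be > 0", call. = FALSE)
  if (contamination_theta <= 0) stop("contamination_theta must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

TRACKED_CO_DRUGS <- c("ceftriaxone", "vancomycin", "cefepime",
                      "piperacillin-tazobactam", "doxycycline", "meropenem")

#' Simulate cohort metadata and antibiotic exposures
#'
#' Draws patients (group membership, covariates, site, batch), antibiotic
#' exposure intervals (azithromycin courses with median 2 days starting in
#' the first hospital week; co-antibiotics with ceftriaxone most frequent)
#' and the sample collection schedule, plus the negative-control sample
#' rows spread over the batches.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return List: `patients` (covariates + group plan), `intervals`
#'   (exposure intervals CSV-shaped), `samples` (sample metadata including
#'   negative controls).
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    n <- cfg$n_patients
    groups <- sample(names(cfg$group_probabilities), n, replace = TRUE,
                     prob = cfg$group_probabilities)
    patients <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      plan_group = groups,
      site_id = sprintf("site%02d", sample.int(cfg$n_sites, n, replace = TRUE)),
      batch = sample(cfg$batches, n, replace = TRUE),
      age_quintile = sample.int(5, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      trajectory_group = sample.int(5, n, replace = TRUE,
                                    prob = c(0.3, 0.25, 0.2, 0.15, 0.1)),
      steroids_ever = stats::rbinom(n, 1, 0.6) == 1
    )

    course <- function(start) {
      dur <- min(35, 1 + stats::rnbinom(1, size = 1, mu = 2))
      c(start, start + dur - 1)
    }
    rows <- list()
    for (i in seq_len(n)) {
      g <- groups[i]
      if (g == "No-Abx") next
      complete <- stats::runif(1) > cfg$incomplete_dates_rate
      if (g == "Azithro") {
        st <- stats::rnbinom(1, size = 2, mu = 1)
        cs <- course(st)
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = patients$patient_id[i], antibiotic = "azithromycin",
          start_day = cs[1], stop_day = cs[2], complete_flag = complete
        )
        co_probs <- c(ceftriaxone = 0.772, vancomycin = 0.194,
                      cefepime = 0.10, `piperacillin-tazobactam` = 0.08,
                      doxycycline = 0.05, meropenem = 0.04)
        for (drug in names(co_probs)) {
          if (stats::runif(1) < co_probs[drug]) {
            cs2 <- course(st + sample(0:2, 1))
            rows[[length(rows) + 1]] <- tibble::tibble(
              patient_id = patients$patient_id[i], antibiotic = drug,
              start_day = cs2[1], stop_day = cs2[2], complete_flag = complete
            )
          }
        }
      } else {
        n_drugs <- 1 + stats::rbinom(1, 2, 0.25)
        drugs <- sample(TRACKED_CO_DRUGS, n_drugs,
                        prob = c(0.45, 0.2, 0.1, 0.1, 0.08, 0.07))
        st <- stats::rnbinom(1, size = 2, mu = 1.5)
        for (drug in drugs) {
          cs <- course(st + sample(0:2, 1))
          rows[[length(rows) + 1]] <- tibble::tibble(
            patient_id = patients$patient_id[i], antibiotic = drug,
            start_day = cs[1], stop_day = cs[2], complete_flag = complete
          )
        }
      }
    }
    intervals <- dplyr::bind_rows(rows)

    keep_visit <- function() c(TRUE, stats::runif(length(cfg$sampling_days) - 1) >
                                 cfg$sample_dropout)
    samp <- list()
    for (i in seq_len(n)) {
      kept <- cfg$sampling_days[keep_visit()]
      samp[[i]] <- tibble::tibble(
        sample_id = sprintf("%s_d%02d", patients$patient_id[i], kept),
        patient_id = patients$patient_id[i],
        site_id = patients$site_id[i],
        batch = patients$batch[i],
        day_from_admission = kept,
        is_negative_control = FALSE
      )
    }
    samples <- dplyr::bind_rows(samp)
    controls <- tibble::tibble(
      sample_id = sprintf("NC%02d", seq_len(cfg$n_negative_controls)),
      patient_id = NA_character_,
      site_id = NA_character_,
      batch = rep(cfg$batches, length.out = cfg$n_negative_controls),
      day_from_admission = NA_integer_,
      is_negative_control = TRUE
    )
    samples <- dplyr::bind_rows(samples, controls)
    sdlog <- sqrt(log(1 + cfg$total_reads_cv^2))
    samples$total_reads <- round(stats::rlnorm(
      nrow(samples), meanlog = log(cfg$total_reads_mean) - sdlog^2 / 2,
      sdlog = sdlog
    ))
    list(patients = patients, intervals = intervals, samples = samples)
  })
}

# AR(1) latent log-abundance deviations for every patient x visit x feature.
ar1_deviations <- function(n_patients, n_visits, n_features, rho, sd) {
  z <- array(0, dim = c(n_patients, n_visits, n_features))
  z[, 1, ] <- stats::rnorm(n_patients * n_features, sd = sd)
  if (n_visits > 1) {
    for (v in 2:n_visits) {
      z[, v, ] <- rho * z[, v - 1, ] +
        sqrt(1 - rho^2) * stats::rnorm(n_patients * n_features, sd = sd)
    }
  }
  z
}

#' Simulate taxon and resistance-gene report tables
#'
#' Generates post-pipeline report tables with the statistical structure
#' the analysis assumes:
#' \itemize{
#'   \item Contaminant features (taxa and genes) are drawn NB(mu_batch,
#'     theta) in negative controls and clinical samples alike; controls
#'     carry nothing else.
#'   \item True taxa follow per-genus log-normal abundance with a patient
#'     offset and AR(1) dependence across visits.
#'   \item Latent MLS gene expression is multiplied by
#'     `azithro_effect^(cumulative azithromycin days at collection)`;
#'     non-MLS classes are untouched. Detection is threshold crossing, so
#'     the effect raises both expression and richness.
#'   \item A `qc_fail_rate` fraction of records is corrupted to fail each
#'     quality-control rule (few NT alignments, short alignments, missing
#'     NR hits; sub-5% coverage breadth with shallow depth).
#' }
#'
#' @param cfg A [sim_config()].
#' @param cohort Output of [simulate_cohort()].
#' @param seed Integer seed.
#' @return List: `taxa` and `args` record tibbles (controls included),
#'   and `truth` (contamination means/theta and the true-feature panels)
#'   for generator-level checks.
#' @export
simulate_reports <- function(cfg, cohort, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    samples <- cohort$samples
    patients <- cohort$patients
    genera <- default_genera()
    genes <- cfg$gene_classes
    contam_taxa <- default_contaminant_taxa()[seq_len(cfg$n_contaminant_taxa)]
    contam_genes <- sprintf("contamARG%d", seq_len(cfg$n_contaminant_genes))

    # --- contamination background (controls + clinical samples) ---
    mu_taxa <- matrix(
      stats::rlnorm(length(cfg$batches) * length(contam_taxa),
                    meanlog = log(20), sdlog = 1),
      nrow = length(cfg$batches),
      dimnames = list(cfg$batches, contam_taxa)
    )
    mu_args <- matrix(
      stats::rlnorm(length(cfg$batches) * length(contam_genes),
                    meanlog = log(15), sdlog = 0.8),
      nrow = length(cfg$batches),
      dimnames = list(cfg$batches, contam_genes)
    )
    contam_counts <- function(mu) {
      t(vapply(seq_len(nrow(samples)), function(i) {
        stats::rnbinom(ncol(mu), size = cfg$contamination_theta,
                       mu = mu[samples$batch[i], ])
      }, numeric(ncol(mu))))
    }
    ct_taxa <- contam_counts(mu_taxa)
    ct_args <- contam_counts(mu_args)

    # --- true taxa in clinical samples ---
    visit_days <- cfg$sampling_days
    mu_genus <- stats::rnorm(nrow(genera),
                             mean = ifelse(genera$kingdom == "bacteria",
                                           log(150), log(30)),
                             sd = 1.2)
    pat_off <- matrix(stats::rnorm(nrow(patients) * nrow(genera), sd = 0.8),
                      nrow = nrow(patients))
    z_tax <- ar1_deviations(nrow(patients), length(visit_days), nrow(genera),
                            cfg$ar1_rho, 0.6)

    clin <- samples[!samples$is_negative_control, ]
    p_idx <- match(clin$patient_id, patients$patient_id)
    v_idx <- match(clin$day_from_admission, visit_days)
    n_clin <- nrow(clin)
    lat_rpm <- matrix(0, n_clin, nrow(genera))
    for (g in seq_len(nrow(genera))) {
      lat_rpm[, g] <- exp(mu_genus[g] + pat_off[cbind(p_idx, g)] +
                            z_tax[cbind(p_idx, v_idx, g)])
    }
    true_reads <- matrix(
      stats::rpois(length(lat_rpm), lat_rpm * clin$total_reads / 1e6),
      n_clin, nrow(genera)
    )

    # --- resistance genes in clinical samples ---
    is_mls <- genes$drug_class == "MLS"
    mu_gene <- stats::rnorm(nrow(genes),
                            mean = ifelse(is_mls, log(0.1), log(0.3)),
                            sd = 1.2)
    pat_off_g <- matrix(stats::rnorm(nrow(patients) * nrow(genes), sd = 0.8),
                        nrow = nrow(patients))
    z_arg <- ar1_deviations(nrow(patients), length(visit_days), nrow(genes),
                            cfg$ar1_rho, 0.6)
    az_days <- lapply(patients$patient_id, function(p) {
      iv <- cohort$intervals
      iv <- iv[iv$patient_id == p & iv$antibiotic == "azithromycin", ]
      if (nrow(iv) == 0) integer(0) else
        sort(unique(unlist(Map(seq, iv$start_day, iv$stop_day))))
    })
    cum_az <- vapply(seq_len(n_clin), function(i) {
      sum(az_days[[p_idx[i]]] <= clin$day_from_admission[i])
    }, numeric(1))
    lat_dpm <- matrix(0, n_clin, nrow(genes))
    for (g in seq_len(nrow(genes))) {
      lat <- exp(mu_gene[g] + pat_off_g[cbind(p_idx, g)] +
                   z_arg[cbind(p_idx, v_idx, g)])
      if (is_mls[g]) lat <- lat * cfg$azithro_effect^cum_az
      lat_dpm[, g] <- lat
    }
    dpm_detect <- 0.2
    detected <- lat_dpm > dpm_detect

    # --- assemble taxon records ---
    tax_rows <- which(true_reads > 0, arr.ind = TRUE)
    taxa_true <- tibble::tibble(
      sample_id = clin$sample_id[tax_rows[, 1]],
      name = genera$name[tax_rows[, 2]],
      kingdom = genera$kingdom[tax_rows[, 2]],
      reads = true_reads[tax_rows]
    )
    clin_all_idx <- which(!samples$is_negative_control)
    ctl_idx <- which(samples$is_negative_control)
    ct_rows <- which(ct_taxa > 0, arr.ind = TRUE)
    taxa_contam <- tibble::tibble(
      sample_id = samples$sample_id[ct_rows[, 1]],
      name = contam_taxa[ct_rows[, 2]],
      kingdom = "bacteria",
      reads = ct_taxa[ct_rows]
    )
    taxa <- dplyr::bind_rows(taxa_true, taxa_contam)
    taxa$rank <- "genus"
    taxa$taxon_id <- paste0("tax_", taxa$name)
    nr <- nrow(taxa)
    taxa$nt_alignments <- pmax(10, round(taxa$reads * stats::runif(nr, 0.8, 1)))
    taxa$nr_alignments <- pmax(1, round(taxa$reads * stats::runif(nr, 0.3, 0.6)))
    taxa$nt_alignment_length <- round(stats::runif(nr, 70, 180))
    # corrupt a fraction per QC rule
    for (rule in c("nt", "nr", "len")) {
      bad <- stats::runif(nr) < cfg$qc_fail_rate
      if (rule == "nt") taxa$nt_alignments[bad] <- sample(0:9, sum(bad), replace = TRUE)
      if (rule == "nr") taxa$nr_alignments[bad] <- 0
      if (rule == "len") taxa$nt_alignment_length[bad] <- round(stats::runif(sum(bad), 20, 49))
    }
    taxa <- taxa[, TAXON_REPORT_COLS]

    # --- assemble ARG records ---
    arg_rows <- which(detected, arr.ind = TRUE)
    dpm <- lat_dpm[arg_rows]
    tot <- clin$total_reads[arg_rows[, 1]]
    mean_depth <- dpm * tot / 1e6
    glen <- genes$gene_length[arg_rows[, 2]]
    reads <- pmax(1, round(mean_depth * glen / 100))
    args_true <- tibble::tibble(
      sample_id = clin$sample_id[arg_rows[, 1]],
      gene = genes$gene[arg_rows[, 2]],
      drug_class = genes$drug_class[arg_rows[, 2]],
      reads = reads,
      alignments = pmax(1, round(reads * stats::runif(length(reads), 0.85, 1))),
      coverage_breadth = pmin(1, 1 - exp(-mean_depth *
                                           stats::runif(length(reads), 1, 3))),
      mean_depth = mean_depth
    )
    ca_rows <- which(ct_args > 0, arr.ind = TRUE)
    ca_reads <- ct_args[ca_rows]
    ca_len <- 900
    ca_depth <- ca_reads * 100 / ca_len
    args_contam <- tibble::tibble(
      sample_id = samples$sample_id[ca_rows[, 1]],
      gene = contam_genes[ca_rows[, 2]],
      drug_class = "other",
      reads = ca_reads,
      alignments = ca_reads,
      coverage_breadth = pmin(1, 1 - exp(-ca_depth)),
      mean_depth = ca_depth
    )
    args <- dplyr::bind_rows(args_true, args_contam)
    na <- nrow(args)
    bad <- stats::runif(na) < cfg$qc_fail_rate
    args$coverage_breadth[bad] <- stats::runif(sum(bad), 0.005, 0.045)
    shallow <- bad & stats::runif(na) < 0.5
    args$mean_depth[shallow] <- stats::runif(sum(shallow), 0.01, 0.5)
    args$alignments[shallow] <- sample(1:10, sum(shallow), replace = TRUE)
    args$reads[shallow] <- args$alignments[shallow]

    list(
      taxa = taxa,
      args = args,
      truth = list(mu_taxa = mu_taxa, mu_args = mu_args,
                   theta = cfg$contamination_theta,
                   true_taxa = genera$name, contaminant_taxa = contam_taxa,
                   contaminant_genes = contam_genes,
                   dpm_detect = dpm_detect)
    )
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_cohort()] and
#' [simulate_reports()] under one seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `patients`, `intervals`, `samples`, `taxa`, `args`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  cohort <- simulate_cohort(cfg, seed = seed)
  reports <- simulate_reports(cfg, cohort, seed = seed + 1e6)
  c(cohort, reports)
}
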