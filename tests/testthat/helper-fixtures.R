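# Small in-code fixtures shared across test files.

tiny_taxon_records <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    taxon_id = c("tax_Staphylococcus", "tax_Candida", "tax_Staphylococcus"),
    name = c("Staphylococcus", "Candida", "Staphylococcus"),
    rank = c("genus", "genus", "genus"),
    kingdom = c("bacteria", "fungi", "bacteria"),
    reads = c(120, 8, 45),
    nt_alignments = c(110, 10, 40),
    nr_alignments = c(60, 2, 18),
    nt_alignment_length = c(140, 95, 120)
  )
}

tiny_arg_records <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    gene = c("ermA", "tetM", "msrA"),
    drug_class = c("MLS", "tetracycline", "MLS"),
    reads = c(30, 12, 5),
    alignments = c(28, 12, 5),
    coverage_breadth = c(0.8, 0.35, 0.12),
    mean_depth = c(4.2, 1.1, 0.4)
  )
}

random_taxon_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    key <- unique(tibble::tibble(
      sample_id = sprintf("S%02d", sample.int(8, n, replace = TRUE)),
      taxon_id = sprintf("tax%03d", sample.int(60, n, replace = TRUE)),
      rank = sample(c("genus", "species"), n, replace = TRUE)
    ))
    m <- nrow(key)
    dplyr::mutate(key,
      name = paste0("Taxon_", sub("tax", "", taxon_id)),
      kingdom = sample(c("bacteria", "fungi", "viruses", "other"), m, TRUE),
      reads = stats::rpois(m, 40),
      nt_alignments = sample(0:80, m, TRUE),
      nr_alignments = sample(0:10, m, TRUE),
      nt_alignment_length = round(stats::runif(m, 20, 200), 1)
    )[, azresistome:::TAXON_REPORT_COLS]
  })
}

small_cfg <- function(...) {
  sim_config(n_patients = 30, sample_dropout = 0.1, ...)
}
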