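#' Per-sample taxon quality filter
#'
#' Removes spurious taxonomic hits surviving decontamination. A record is
#' retained only when it has at least 10 nucleotide-database alignments, at
#' least 1 protein-database alignment, and a mean nucleotide alignment
#' length of at least 50 bases; all three inequalities are inclusive.
#'
#' @param records Tibble of taxon records.
#' @return List with `retained` (the surviving records) and `decisions`
#'   (one row per input record: `retained` flag and the comma-separated
#'   identifiers of failed rules, empty when retained).
#' @export
filter_taxa <- function(records) {
  n <- nrow(records)
  f_nt <- records$nt_alignments < 10
  f_nr <- records$nr_alignments < 1
  f_len <- records$nt_alignment_length < 50
  failed_rules <- mapply(function(a, b, c) {
    paste(c(if (a) "nt_alignments", if (b) "nr_alignments",
            if (c) "nt_alignment_length"), collapse = ",")
  }, f_nt, f_nr, f_len)
  if (n == 0) failed_rules <- character(0)
  retained <- !(f_nt | f_nr | f_len)
  decisions <- tibble::tibble(
    sample_id = records$sample_id,
    taxon_id = records$taxon_id,
    rank = records$rank,
    retained = retained,
    failed_rules = failed_rules
  )
  list(retained = records[retained, , drop = FALSE], decisions = decisions)
}

#' Cohort prevalence of resistance genes
#'
#' Fraction of ARG-bearing samples (samples with at least one ARG record)
#' in which each gene is detected. This is the denominator convention of
#' the per-sample ARG filter: prevalence is computed once, over the whole
#' cohort, before filtering.
#'
#' @param records Tibble of ARG records (post-decontamination).
#' @return Named numeric vector, gene -> fraction in \[0, 1\].
#' @export
arg_prevalence <- function(records) {
  n_samples <- dplyr::n_distinct(records$sample_id)
  if (n_samples == 0) return(setNames(numeric(0), character(0)))
  det <- dplyr::distinct(records, .data$sample_id, .data$gene)
  tab <- table(det$gene)
  setNames(as.numeric(tab) / n_samples, names(tab))
}

#' Per-sample resistance-gene quality filter
#'
#' A record is excluded iff its coverage breadth is below 5% AND either the
#' gene is detected in at most 5% of ARG-bearing samples, or it has both
#' DPM of at most 1 and at most 10 alignments to the resistance database.
#' Adequate coverage breadth alone therefore rescues a rare or shallow hit.
#'
#' @param records Tibble of ARG records carrying a `dpm` column (see
#'   [add_abundance()]).
#' @param prevalence Named gene -> fraction map from [arg_prevalence()];
#'   every gene in `records` must be present.
#' @return List with `retained` records and per-record `decisions`
#'   (`retained`, `failed_rules` naming the exclusion arm(s) that fired).
#' @export
filter_args <- function(records, prevalence) {
  check_columns(records, c("sample_id", "gene", "coverage_breadth",
                           "alignments", "dpm"), "ARG records")
  missing <- setdiff(unique(records$gene), names(prevalence))
  if (length(missing) > 0) {
    stop("gene(s) missing from the prevalence map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prev <- unname(prevalence[records$gene])
  low_cov <- records$coverage_breadth < 0.05
  rare <- prev <= 0.05
  shallow <- records$dpm <= 1 & records$alignments <= 10
  excluded <- low_cov & (rare | shallow)
  failed_rules <- character(nrow(records))
  hit_rare <- low_cov & rare
  hit_shallow <- low_cov & shallow
  failed_rules[hit_rare & hit_shallow] <- "low_coverage+low_prevalence,low_coverage+low_depth"
  failed_rules[hit_rare & !hit_shallow] <- "low_coverage+low_prevalence"
  failed_rules[!hit_rare & hit_shallow] <- "low_coverage+low_depth"
  decisions <- tibble::tibble(
    sample_id = records$sample_id,
    gene = records$gene,
    retained = !excluded,
    failed_rules = failed_rules
  )
  list(retained = records[!excluded, , drop = FALSE], decisions = decisions)
}
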