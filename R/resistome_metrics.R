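#' MLS resistance-gene richness of one sample
#'
#' Number of distinct macrolide/lincosamide/streptogramin (MLS) resistance
#' genes detectably expressed in a sample, i.e. with positive DPM after
#' the full decontamination and quality-filter cascade. No further
#' detection threshold is applied.
#'
#' @param records ARG records of one sample (post-filtering) with `gene`,
#'   `drug_class` and `dpm` columns.
#' @return Integer count (0 for an empty resistome).
#' @export
mls_richness <- function(records) {
  if (nrow(records) == 0) return(0L)
  length(unique(records$gene[records$drug_class == "MLS" & records$dpm > 0]))
}

#' Per-class proportional representation of a sample's resistome
#'
#' Fraction of total DPM contributed by each drug class. Undefined when
#' the sample carries no DPM at all; that case returns an empty vector
#' with attribute `undefined = TRUE` rather than silent zeros.
#'
#' @param records ARG records of one sample with `drug_class` and `dpm`.
#' @return Named numeric vector of fractions summing to 1, or the flagged
#'   empty vector.
#' @export
class_proportions <- function(records) {
  total <- sum(records$dpm)
  if (nrow(records) == 0 || total == 0) {
    out <- numeric(0)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  agg <- tapply(records$dpm, records$drug_class, sum)
  setNames(as.numeric(agg) / total, names(agg))
}

#' Per-sample resistome profiles for a cohort
#'
#' Convenience wrapper computing MLS richness, total DPM and the MLS
#' proportion for every sample in a filtered ARG record table.
#'
#' @param records Filtered ARG records with `sample_id`, `gene`,
#'   `drug_class`, `dpm`.
#' @param sample_ids Optional sample universe; samples without records get
#'   richness 0 and `NA` proportions.
#' @return Tibble: `sample_id`, `mls_richness`, `total_dpm`,
#'   `mls_proportion`.
#' @export
resistome_profiles <- function(records, sample_ids = NULL) {
  ids <- sample_ids %||% sort(unique(records$sample_id))
  per <- lapply(ids, function(s) {
    rec <- records[records$sample_id == s, , drop = FALSE]
    props <- class_proportions(rec)
    tibble::tibble(
      sample_id = s,
      mls_richness = mls_richness(rec),
      total_dpm = sum(rec$dpm),
      mls_proportion = if (length(props) == 0) NA_real_ else
        unname(props["MLS"] %|NA|% 0)
    )
  })
  dplyr::bind_rows(per)
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Post-cessation persistence window
#'
#' Selects, for one azithromycin-exposed patient, the samples collected 7
#' to 10 days after the last azithromycin dose — the window used to ask
#' whether exposure-associated resistome changes outlast the drug.
#'
#' @param sample_days Integer days-from-admission of the patient's samples.
#' @param cessation_day Last azithromycin exposure day; `NA` or missing
#'   exposure is an error (the window is undefined for unexposed patients).
#' @return Logical vector marking the samples inside the window; attribute
#'   `empty_window = TRUE` when no sample falls in it.
#' @export
persistence_window <- function(sample_days, cessation_day) {
  if (length(cessation_day) != 1 || is.na(cessation_day)) {
    stop("patient has no azithromycin exposure; persistence window undefined",
         call. = FALSE)
  }
  delta <- sample_days - cessation_day
  sel <- delta >= 7 & delta <= 10
  if (!any(sel)) attr(sel, "empty_window") <- TRUE
  sel
}
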