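#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Column contracts for the two report dialects. coverage_breadth is carried
# internally as a fraction in [0,1]; the ARG dialect prints percent.
TAXON_REPORT_COLS <- c(
  "sample_id", "taxon_id", "name", "rank", "kingdom",
  "reads", "nt_alignments", "nr_alignments", "nt_alignment_length"
)
ARG_REPORT_COLS <- c(
  "sample_id", "gene", "drug_class", "reads", "alignments",
  "coverage_breadth_pct", "mean_depth"
)
TAXON_RANKS <- c("species", "genus")
TAXON_KINGDOMS <- c("bacteria", "fungi", "viruses", "other")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(msg) stop("schema error: ", msg, call. = FALSE)
stop_validation <- function(msg) stop("validation error: ", msg, call. = FALSE)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

parse_numeric_strict <- function(x, column, what) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0 || anyNA(x)) {
    stop_schema(sprintf(
      "%s column '%s' contains unparseable numeric value(s), e.g. row %d: '%s'",
      what, column, c(bad, which(is.na(x)))[1],
      as.character(x[c(bad, which(is.na(x)))[1]])
    ))
  }
  out
}

#' Read a per-sample taxon report table
#'
#' Reads the tab-separated taxon report dialect produced downstream of a
#' metagenomic classification pipeline: one row per (sample, taxon, rank)
#' with read counts, nucleotide/protein alignment counts and the mean
#' nucleotide alignment length in bases.
#'
#' @param path Path to a TSV file with columns `sample_id`, `taxon_id`,
#'   `name`, `rank`, `kingdom`, `reads`, `nt_alignments`, `nr_alignments`,
#'   `nt_alignment_length`.
#' @return A tibble with one row per record. Numeric columns are strictly
#'   parsed: unparseable values (including `NA`) are an error, never a
#'   silent zero.
#' @export
read_taxon_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, TAXON_REPORT_COLS, "taxon report")
  if (nrow(raw) == 0) return(empty_taxon_report())
  num_cols <- c("reads", "nt_alignments", "nr_alignments", "nt_alignment_length")
  for (cl in num_cols) raw[[cl]] <- parse_numeric_strict(raw[[cl]], cl, "taxon report")
  out <- validate_taxon_records(tibble::as_tibble(raw[TAXON_REPORT_COLS]))
  out
}

empty_taxon_report <- function() {
  tibble::tibble(
    sample_id = character(), taxon_id = character(), name = character(),
    rank = character(), kingdom = character(), reads = numeric(),
    nt_alignments = numeric(), nr_alignments = numeric(),
    nt_alignment_length = numeric()
  )
}

#' Validate taxon records
#'
#' Enforces the taxon-record invariants: known rank and kingdom levels,
#' non-negative counts and lengths, and uniqueness of
#' (sample_id, taxon_id, rank).
#'
#' @param records A tibble of taxon records.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_taxon_records <- function(records) {
  check_columns(records, TAXON_REPORT_COLS, "taxon records")
  bad_rank <- setdiff(unique(records$rank), TAXON_RANKS)
  if (length(bad_rank) > 0) {
    stop_validation(paste0("unknown rank level(s): ", paste(bad_rank, collapse = ", ")))
  }
  bad_kingdom <- setdiff(unique(records$kingdom), TAXON_KINGDOMS)
  if (length(bad_kingdom) > 0) {
    stop_validation(paste0("unknown kingdom level(s): ", paste(bad_kingdom, collapse = ", ")))
  }
  for (cl in c("reads", "nt_alignments", "nr_alignments", "nt_alignment_length")) {
    if (any(records[[cl]] < 0)) stop_validation(paste0("negative values in ", cl))
  }
  key <- paste(records$sample_id, records$taxon_id, records$rank, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (sample_id, taxon_id, rank) record(s)")
  }
  records
}

#' Write a taxon report table
#'
#' @param records Tibble of taxon records (see [read_taxon_report()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxon_report <- function(records, path) {
  check_columns(records, TAXON_REPORT_COLS, "taxon records")
  readr::write_tsv(records[TAXON_REPORT_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample antimicrobial resistance gene report
#'
#' Reads the resistance-gene report dialect (one row per gene per sample,
#' with read counts, alignment counts, coverage breadth in percent and mean
#' per-base depth). Coverage breadth is converted on input to a fraction in
#' \[0, 1\]; [write_arg_report()] converts back to percent.
#'
#' @param path Path to a TSV with columns `sample_id`, `gene`,
#'   `drug_class`, `reads`, `alignments`, `coverage_breadth_pct`,
#'   `mean_depth`.
#' @return Tibble with a `coverage_breadth` fraction column in place of the
#'   percent column.
#' @export
read_arg_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, ARG_REPORT_COLS, "ARG report")
  num_cols <- c("reads", "alignments", "coverage_breadth_pct", "mean_depth")
  for (cl in num_cols) raw[[cl]] <- parse_numeric_strict(raw[[cl]], cl, "ARG report")
  out <- tibble::as_tibble(raw[ARG_REPORT_COLS])
  out$coverage_breadth <- out$coverage_breadth_pct / 100
  out$coverage_breadth_pct <- NULL
  validate_arg_records(out)
}

#' Validate resistance-gene records
#'
#' Enforces coverage breadth within \[0, 1\], non-negative counts and
#' depths, the depth/reads zero-coupling (`mean_depth == 0` exactly when
#' `reads == 0`), and per-sample gene uniqueness.
#'
#' @param records Tibble of ARG records with a `coverage_breadth` fraction.
#' @return The validated tibble.
#' @export
validate_arg_records <- function(records) {
  needed <- c("sample_id", "gene", "drug_class", "reads", "alignments",
              "coverage_breadth", "mean_depth")
  check_columns(records, needed, "ARG records")
  if (any(records$coverage_breadth < 0 | records$coverage_breadth > 1)) {
    stop_validation("coverage_breadth outside [0, 1]")
  }
  if (any(records$reads < 0) || any(records$mean_depth < 0) ||
      any(records$alignments < 0)) {
    stop_validation("negative counts or depths in ARG records")
  }
  if (any((records$mean_depth == 0) != (records$reads == 0))) {
    stop_validation("mean_depth must be zero exactly when reads is zero")
  }
  key <- paste(records$sample_id, records$gene, sep = "\r")
  if (anyDuplicated(key)) stop_validation("duplicate (sample_id, gene) record(s)")
  records
}

#' Write a resistance-gene report table
#'
#' @param records Tibble of ARG records carrying a `coverage_breadth`
#'   fraction column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_arg_report <- function(records, path) {
  out <- records
  out$coverage_breadth_pct <- out$coverage_breadth * 100
  out$coverage_breadth <- NULL
  readr::write_tsv(out[ARG_REPORT_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' One row per sequenced sample: patient, site, sequencing batch
#' (study phase 1, 2, 3A or 3B), day from admission, the per-sample
#' post-host-removal microbial read total used as the normalisation
#' denominator, and a negative-control flag. Extra clinical covariate
#' columns are carried through untouched.
#'
#' @param path CSV path.
#' @return Validated tibble; negative controls must carry no patient id and
#'   every sample must have `total_reads > 0`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

#' Validate sample metadata
#' @param meta Tibble with at least `sample_id`, `batch`, `total_reads`,
#'   `is_negative_control`, and `patient_id`.
#' @return The validated tibble.
#' @export
validate_sample_metadata <- function(meta) {
  check_columns(meta, c("sample_id", "patient_id", "batch", "total_reads",
                        "is_negative_control"), "sample metadata")
  if (anyDuplicated(meta$sample_id)) stop_validation("duplicate sample_id")
  if (any(meta$total_reads <= 0)) stop_validation("total_reads must be positive")
  ctrl <- meta$is_negative_control
  if (any(ctrl & !is.na(meta$patient_id))) {
    stop_validation("negative controls must not carry a patient_id")
  }
  meta
}

#' Reads-per-million normalisation
#'
#' RPM = reads x 1e6 / total_reads, the depth-normalised abundance used for
#' taxon counts.
#'
#' @param reads Non-negative read count (vectorised).
#' @param total_reads Positive per-sample total microbial reads.
#' @return RPM values.
#' @export
#' @examples
#' compute_rpm(50, 2e6) # 25
compute_rpm <- function(reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0", call. = FALSE)
  if (any(reads < 0)) stop("reads must be >= 0", call. = FALSE)
  reads * 1e6 / total_reads
}

#' Depth-per-million normalisation
#'
#' DPM = mean per-base depth x 1e6 / total_reads. Normalises a gene's mean
#' sequencing depth for per-sample sequencing effort; because mean depth is
#' already averaged over gene length, DPM is comparable across genes of
#' different lengths.
#'
#' @param mean_depth Non-negative mean per-base depth over the gene.
#' @param total_reads Positive per-sample total microbial reads.
#' @return DPM values.
#' @export
#' @examples
#' compute_dpm(3, 1.5e6) # 2
compute_dpm <- function(mean_depth, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0", call. = FALSE)
  if (any(mean_depth < 0)) stop("mean_depth must be >= 0", call. = FALSE)
  mean_depth * 1e6 / total_reads
}

#' Construct a samples x features abundance table
#'
#' @param mat Numeric matrix, samples in rows, features in columns, with
#'   unique dimnames.
#' @param value_kind One of `"reads"`, `"rpm"`, `"dpm"`.
#' @return A `feature_table` object (matrix with a `value_kind` attribute).
#' @export
feature_table <- function(mat, value_kind = c("reads", "rpm", "dpm")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("mat must carry sample and feature names", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop_validation("feature_table identifiers must be unique")
  }
  if (any(mat < 0)) stop_validation("feature_table values must be non-negative")
  structure(mat, value_kind = value_kind, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d samples x %d features, values = %s>\n",
              nrow(x), ncol(x), attr(x, "value_kind")))
  invisible(x)
}

value_kind <- function(x) attr(x, "value_kind")

#' Pivot long records to a samples x features table
#'
#' Missing (sample, feature) pairs become exact zeros; conflicting
#' duplicate records are an error. For a reads-kind table the row sums
#' equal the per-sample sums of the input records.
#'
#' @param records Long tibble.
#' @param feature_col Name of the feature identifier column (e.g. `"name"`
#'   for taxa, `"gene"` for ARGs).
#' @param value_col Name of the value column to spread.
#' @param value_kind Tag for the resulting table.
#' @return A [feature_table()].
#' @export
pivot_to_table <- function(records, feature_col, value_col,
                           value_kind = c("reads", "rpm", "dpm")) {
  value_kind <- match.arg(value_kind)
  check_columns(records, c("sample_id", feature_col, value_col), "records")
  key <- paste(records$sample_id, records[[feature_col]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_validation(paste0("conflicting duplicate record for (sample, feature) = (",
                           gsub("\r", ", ", dup), ")"))
  }
  samples <- sort(unique(records$sample_id))
  features <- sort(unique(records[[feature_col]]))
  mat <- matrix(0, nrow = length(samples), ncol = length(features),
                dimnames = list(samples, features))
  mat[cbind(match(records$sample_id, samples),
            match(records[[feature_col]], features))] <- records[[value_col]]
  feature_table(mat, value_kind)
}

#' Add RPM and DPM columns to report records
#'
#' Joins the per-sample `total_reads` denominator from the metadata and
#' computes `rpm` (taxon records, from `reads`) or `dpm` (ARG records, from
#' `mean_depth`).
#'
#' @param records Taxon or ARG record tibble.
#' @param meta Sample metadata with `sample_id` and `total_reads`.
#' @return `records` with the normalised column appended.
#' @export
add_abundance <- function(records, meta) {
  check_columns(meta, c("sample_id", "total_reads"), "metadata")
  idx <- match(records$sample_id, meta$sample_id)
  if (anyNA(idx)) {
    stop_validation(paste0("sample(s) absent from metadata: ",
                           paste(unique(records$sample_id[is.na(idx)]), collapse = ", ")))
  }
  denom <- meta$total_reads[idx]
  if ("mean_depth" %in% names(records)) {
    records$dpm <- compute_dpm(records$mean_depth, denom)
  } else {
    records$rpm <- compute_rpm(records$reads, denom)
  }
  records
}
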