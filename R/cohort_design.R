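#' Expand antibiotic exposure intervals to per-patient day sets
#'
#' Exposure intervals come in one row per (patient, antibiotic, course):
#' `start_day`, `stop_day` inclusive, on the days-from-admission clock,
#' plus a `complete_flag` marking whether start and stop dates were fully
#' captured. Patients with any incompletely captured course are flagged so
#' group assignment can exclude them.
#'
#' @param intervals Tibble with `patient_id`, `antibiotic`, `start_day`,
#'   `stop_day`, `complete_flag`.
#' @return Tibble, one row per patient: `azithro_days` and `other_abx_days`
#'   (list-columns of integer day sets), `complete_dates`.
#' @export
expand_exposures <- function(intervals) {
  check_columns(intervals, c("patient_id", "antibiotic", "start_day",
                             "stop_day", "complete_flag"), "exposure intervals")
  days_for <- function(sel) {
    if (nrow(sel) == 0) return(integer(0))
    sort(unique(unlist(Map(seq, sel$start_day, sel$stop_day))))
  }
  per <- lapply(split(intervals, intervals$patient_id), function(df) {
    tibble::tibble(
      patient_id = df$patient_id[1],
      azithro_days = list(days_for(df[df$antibiotic == "azithromycin", ])),
      other_abx_days = list(days_for(df[df$antibiotic != "azithromycin", ])),
      complete_dates = all(df$complete_flag)
    )
  })
  dplyr::bind_rows(per)
}

#' Assign patients to antibiotic exposure groups
#'
#' Any azithromycin exposure (with or without other antibiotics) makes a
#' patient Azithro; otherwise any antibiotic makes them Other-Abx;
#' otherwise No-Abx. Patients with incompletely captured start/stop dates
#' are excluded (`group = NA`, reason recorded).
#'
#' @param exposures Tibble from [expand_exposures()], or any tibble with
#'   `patient_id`, list-columns `azithro_days` and `other_abx_days`, and
#'   `complete_dates`. Patients absent from the exposure table are No-Abx
#'   by construction if passed with empty day sets.
#' @return `exposures` with `group` (factor Azithro / Other-Abx / No-Abx)
#'   and `exclusion_reason` columns added.
#' @export
assign_exposure_group <- function(exposures) {
  n_az <- vapply(exposures$azithro_days, length, integer(1))
  n_other <- vapply(exposures$other_abx_days, length, integer(1))
  group <- ifelse(n_az > 0, "Azithro", ifelse(n_other > 0, "Other-Abx", "No-Abx"))
  group[!exposures$complete_dates] <- NA
  exposures$group <- factor(group, levels = c("Azithro", "Other-Abx", "No-Abx"))
  exposures$exclusion_reason <- ifelse(exposures$complete_dates, "",
                                       "incomplete_dates")
  exposures
}

cumulative_exposure <- function(days_set, collection_day) {
  sum(days_set <= collection_day)
}

#' Build the single-timepoint analysis design
#'
#' Assigns every sample to the early (1 +/- 1 days of exposure) or late
#' (5 +/- 1 days) analysis window, or excludes it, following the matching
#' scheme of the single-timepoint analyses:
#' \itemize{
#'   \item Treated samples (Azithro or Other-Abx patients) enter the early
#'     window when cumulative exposure at collection is 1-2 days and the
#'     late window at 4-6 days; a treated sample collected before any
#'     exposure is moved to the No-Abx pool and flagged `reassigned`.
#'   \item No-Abx candidates: early window requires no exposure and at most
#'     40 days of hospitalisation; late window requires no exposure and
#'     3-40 days. Samples qualifying for both are split evenly by
#'     alternation over sorted sample ids.
#'   \item The No-Abx pool in each window is then rarefied to 50%
#'     (discarding floor(n/2) samples uniformly at random, seeded) to keep
#'     group sizes comparable.
#' }
#'
#' @param samples Sample metadata tibble (`sample_id`, `patient_id`,
#'   `day_from_admission`; negative controls excluded by the caller).
#' @param exposures Output of [assign_exposure_group()].
#' @param seed Integer seed for the rarefaction draw.
#' @return Tibble, one row per sample: `group` (effective group),
#'   `original_group`, `window` ("early", "late" or "none"), `included`,
#'   `exclusion_reason`, `reassigned`, `cumulative_exposure_days`.
#' @export
build_analysis_design <- function(samples, exposures, seed = 1) {
  check_columns(samples, c("sample_id", "patient_id", "day_from_admission"),
                "sample metadata")
  idx <- match(samples$patient_id, exposures$patient_id)
  if (anyNA(idx)) {
    stop("patient(s) missing from exposure table: ",
         paste(unique(samples$patient_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  des <- tibble::tibble(
    sample_id = samples$sample_id,
    patient_id = samples$patient_id,
    day = samples$day_from_admission,
    original_group = as.character(exposures$group[idx]),
    group = as.character(exposures$group[idx]),
    window = "none",
    included = FALSE,
    exclusion_reason = "",
    reassigned = FALSE,
    cumulative_exposure_days = NA_integer_
  )
  incomplete <- is.na(des$original_group)
  des$exclusion_reason[incomplete] <- "incomplete_dates"

  treated <- !incomplete & des$original_group %in% c("Azithro", "Other-Abx")
  rel_days <- function(i) {
    e <- exposures[idx[i], ]
    if (des$original_group[i] == "Azithro") e$azithro_days[[1]]
    else sort(unique(c(e$azithro_days[[1]], e$other_abx_days[[1]])))
  }
  for (i in which(treated)) {
    ce <- cumulative_exposure(rel_days(i), des$day[i])
    des$cumulative_exposure_days[i] <- ce
    if (ce == 0) {
      des$group[i] <- "No-Abx"
      des$reassigned[i] <- TRUE
    } else if (ce %in% 1:2) {
      des$window[i] <- "early"; des$included[i] <- TRUE
    } else if (ce %in% 4:6) {
      des$window[i] <- "late"; des$included[i] <- TRUE
    } else {
      des$exclusion_reason[i] <- "exposure_outside_windows"
    }
  }
  des$cumulative_exposure_days[!incomplete & des$group == "No-Abx" &
                                 !des$reassigned] <- 0L

  # No-Abx window qualification and even split of dual qualifiers.
  noabx <- which(!incomplete & des$group == "No-Abx")
  q_early <- des$day[noabx] <= 40
  q_late <- des$day[noabx] >= 3 & des$day[noabx] <= 40
  both <- noabx[q_early & q_late]
  only_early <- noabx[q_early & !q_late]
  only_late <- noabx[!q_early & q_late]
  neither <- noabx[!q_early & !q_late]
  des$exclusion_reason[neither] <- "day_outside_windows"
  des$window[only_early] <- "early"
  des$window[only_late] <- "late"
  both <- both[order(des$sample_id[both])]
  if (length(both) > 0) {
    alt <- rep(c("early", "late"), length.out = length(both))
    des$window[both] <- alt
  }
  qualified <- c(only_early, only_late, both)
  des$included[qualified] <- TRUE

  # 50% rarefaction of the No-Abx pool within each window.
  withr::with_seed(seed, {
    for (w in c("early", "late")) {
      pool <- which(des$group == "No-Abx" & des$window == w & des$included)
      n_drop <- floor(length(pool) / 2)
      if (n_drop > 0) {
        drop <- sample(pool, n_drop)
        des$included[drop] <- FALSE
        des$window[drop] <- "none"
        des$exclusion_reason[drop] <- "rarefied"
      }
    }
  })
  des
}

#' Select the samples of one analysis window
#'
#' @param design Output of [build_analysis_design()].
#' @param window `"early"` or `"late"`.
#' @return The included rows of `design` for that window.
#' @export
select_window_samples <- function(design, window) {
  if (!window %in% c("early", "late")) {
    stop("window must be 'early' or 'late'", call. = FALSE)
  }
  design[design$included & design$window == window, , drop = FALSE]
}

#' Summarise exposure-group membership of a cohort
#'
#' @param groups Vector of per-patient group labels (NA = excluded).
#' @return Tibble with per-group `n` and `pct` (percent of the graded
#'   cohort, rounded to 1 decimal), plus the cohort total as an attribute.
#' @export
#' @examples
#' summarize_cohort(rep(c("Azithro", "No-Abx", "Other-Abx"), c(366, 474, 324)))
summarize_cohort <- function(groups) {
  groups <- groups[!is.na(groups)]
  total <- length(groups)
  tab <- table(groups)
  out <- tibble::tibble(
    group = names(tab),
    n = as.integer(tab),
    pct = round(100 * as.integer(tab) / total, 1)
  )
  attr(out, "total") <- total
  out
}
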