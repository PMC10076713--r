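# Clinical table (cohort) parsing, validation and descriptives.

RECIST_LEVELS <- c("CR", "PR", "SD", "PD")
GENDER_LEVELS <- c("male", "female")

#' Read and validate a clinical table
#'
#' Parses a tab- or comma-separated clinical table with one row per patient.
#' The schema mirrors a basket-trial demographics table: patient id, gender,
#' age, diagnosis code (e.g. BLCA, BRCA), treatment regimen label, best
#' RECIST 1.1 response, biopsy site and number of prior treatment lines.
#' Survival fields (`pfs_time`, `pfs_event`, `os_time`, `os_event`) are
#' optional extensions; survival analyses require them explicitly.
#'
#' Rows with unparseable required fields are rejected with an error rather
#' than silently dropped.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param col_map optional named character vector mapping the canonical
#'   column names (names of the vector) to the column names used in the
#'   file (values), e.g. `c(patient_id = "Id", recist = "RECIST")`.
#' @param time_unit unit of the survival time columns, `"months"` or
#'   `"days"`; recorded as metadata on the returned cohort.
#' @param sep field separator; guessed from the file extension by default.
#' @return an object of class `icb_cohort`: a list with elements
#'   `records` (a validated data frame) and `time_unit`.
#' @export
#' @examples
#' path <- system.file("extdata", "clinical_table1.tsv", package = "icbcombo")
#' cohort <- read_clinical_table(path)
#' nrow(cohort$records)
read_clinical_table <- function(path, col_map = NULL,
                                time_unit = c("months", "days"),
                                sep = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) {
    stop_icb(sprintf("clinical table not found: %s", path),
             "icbcombo_io_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- tryCatch(
    read.delim(path, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) {
      stop_icb(sprintf("could not parse clinical table: %s",
                       conditionMessage(e)), "icbcombo_schema_error")
    }
  )
  if (nrow(df) == 0L || ncol(df) <= 1L && nrow(df) == 0L) {
    stop_icb("clinical table is empty", "icbcombo_schema_error")
  }

  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop_icb(sprintf("mapped column '%s' (for '%s') not in file",
                         src, canon), "icbcombo_schema_error")
      }
      names(df)[names(df) == src] <- canon
    }
  }

  required <- c("patient_id", "gender", "age", "diagnosis", "treatment",
                "recist", "biopsy_site", "prior_treatments")
  assert_columns(df, required, "clinical table")
  df$patient_id <- as.character(df$patient_id)
  df$gender <- tolower(trimws(df$gender))
  df$recist <- toupper(trimws(df$recist))
  df$age <- suppressWarnings(as.numeric(df$age))
  df$prior_treatments <- suppressWarnings(as.numeric(df$prior_treatments))

  validate_clinical(df)

  optional <- c("pfs_time", "pfs_event", "os_time", "os_event")
  for (col in intersect(optional, names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (all(c("pfs_time", "os_time") %in% names(df))) {
    both <- !is.na(df$pfs_time) & !is.na(df$os_time)
    if (any(df$pfs_time[both] > df$os_time[both])) {
      bad <- df$patient_id[both][df$pfs_time[both] > df$os_time[both]]
      stop_icb(sprintf("pfs_time exceeds os_time for patient(s): %s",
                       paste(bad, collapse = ", ")),
               "icbcombo_validation_error")
    }
  }

  structure(list(records = df, time_unit = time_unit),
            class = "icb_cohort")
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop_icb(sprintf("duplicate patient_id: %s", paste(dup, collapse = ", ")),
             "icbcombo_validation_error")
  }
  if (any(is.na(df$age)) || any(df$age <= 0)) {
    stop_icb("age must be a positive number for every patient",
             "icbcombo_validation_error")
  }
  if (any(is.na(df$prior_treatments)) || any(df$prior_treatments < 0)) {
    stop_icb("prior_treatments must be a non-negative number",
             "icbcombo_validation_error")
  }
  bad_recist <- setdiff(unique(df$recist), RECIST_LEVELS)
  if (length(bad_recist) > 0L) {
    stop_icb(sprintf("invalid RECIST value(s): %s (allowed: %s)",
                     paste(bad_recist, collapse = ", "),
                     paste(RECIST_LEVELS, collapse = ", ")),
             "icbcombo_validation_error")
  }
  bad_gender <- setdiff(unique(df$gender), GENDER_LEVELS)
  if (length(bad_gender) > 0L) {
    stop_icb(sprintf("invalid gender value(s): %s",
                     paste(bad_gender, collapse = ", ")),
             "icbcombo_validation_error")
  }
  invisible(df)
}

#' Clinical-benefit grouping from RECIST response
#'
#' Progressive disease (PD) defines the progressive group; CR, PR and SD
#' together form the non-progressive (clinical benefit) group.
#'
#' @param x an `icb_cohort`, a data frame with a `recist` column, or a
#'   character vector of RECIST codes.
#' @return a character vector in `{"progressive", "non_progressive"}`.
#' @export
#' @examples
#' benefit_group(c("PD", "CR", "SD"))
benefit_group <- function(x) {
  recist <- if (inherits(x, "icb_cohort")) {
    x$records$recist
  } else if (is.data.frame(x)) {
    assert_columns(x, "recist")
    x$recist
  } else {
    toupper(trimws(as.character(x)))
  }
  bad <- setdiff(unique(recist[!is.na(recist)]), RECIST_LEVELS)
  if (length(bad) > 0L) {
    stop_icb(sprintf("invalid RECIST value(s): %s", paste(bad, collapse = ", ")),
             "icbcombo_validation_error")
  }
  ifelse(recist == "PD", "progressive", "non_progressive")
}

# normalized regimen label: trimmed, case-folded, whitespace collapsed
normalize_regimen <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Classify a regimen by the checkpoint axis it blocks
#'
#' A regimen containing Pembrolizumab or Nivolumab targets PD-1; otherwise
#' one containing Atezolizumab targets PD-L1; anything else is `"other"`.
#'
#' @param treatment character vector of regimen labels.
#' @return character vector in `{"PD-1", "PD-L1", "other"}`.
#' @export
checkpoint_axis <- function(treatment) {
  lab <- normalize_regimen(treatment)
  ifelse(grepl("pembrolizumab|nivolumab", lab), "PD-1",
         ifelse(grepl("atezolizumab", lab), "PD-L1", "other"))
}

#' Cohort descriptives
#'
#' Deterministic summaries of the clinical table: patient count, sex
#' counts, age (mean raw and rounded to the nearest integer, min, max),
#' prior treatment lines (mean raw and to one decimal, min, max), RECIST
#' distribution, number of distinct diagnoses and distinct treatment
#' regimens (exact normalized string match), and counts per checkpoint
#' axis (PD-1 vs PD-L1).
#'
#' @param cohort an `icb_cohort` or a clinical data frame.
#' @return a list of class `icb_cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  df <- if (inherits(cohort, "icb_cohort")) cohort$records else cohort
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_icb("summarize_cohort requires a non-empty cohort",
             "icbcombo_validation_error")
  }
  recist_counts <- table(factor(df$recist, levels = RECIST_LEVELS))
  sex_counts <- table(factor(df$gender, levels = GENDER_LEVELS))
  axis <- checkpoint_axis(df$treatment)
  axis_counts <- table(factor(axis, levels = c("PD-1", "PD-L1", "other")))
  out <- list(
    n = nrow(df),
    sex_counts = as.list(sex_counts),
    age_mean = mean(df$age),
    age_mean_rounded = round(mean(df$age)),
    age_min = min(df$age),
    age_max = max(df$age),
    prior_mean = mean(df$prior_treatments),
    prior_mean_rounded = round(mean(df$prior_treatments), 1),
    prior_min = min(df$prior_treatments),
    prior_max = max(df$prior_treatments),
    recist_counts = as.list(recist_counts),
    n_diagnoses = length(unique(trimws(df$diagnosis))),
    n_regimens = length(unique(normalize_regimen(df$treatment))),
    axis_counts = as.list(axis_counts)
  )
  class(out) <- "icb_cohort_summary"
  out
}

#' @export
print.icb_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d male / %d female)\n", x$n,
              x$sex_counts$male, x$sex_counts$female))
  cat(sprintf("Age: mean %d (range %g-%g)\n", x$age_mean_rounded,
              x$age_min, x$age_max))
  cat(sprintf("Prior treatment lines: mean %.1f (range %g-%g)\n",
              x$prior_mean_rounded, x$prior_min, x$prior_max))
  cat(sprintf("RECIST: CR %d, PR %d, SD %d, PD %d\n",
              x$recist_counts$CR, x$recist_counts$PR,
              x$recist_counts$SD, x$recist_counts$PD))
  cat(sprintf("%d distinct diagnoses, %d distinct regimens\n",
              x$n_diagnoses, x$n_regimens))
  cat(sprintf("Checkpoint axis: PD-1 %d, PD-L1 %d, other %d\n",
              x$axis_counts[["PD-1"]], x$axis_counts[["PD-L1"]],
              x$axis_counts[["other"]]))
  invisible(x)
}
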