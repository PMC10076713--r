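# Median dichotomization and combined-biomarker group assignment.

BIOMARKERS <- c("neoload", "pdl2", "cyt", "tdiv")
BIOMARKER_LABELS <- c(neoload = "NeoLoad", pdl2 = "PDL2",
                      cyt = "CYT", tdiv = "Tdiv")

#' Median dichotomization of one biomarker
#'
#' Splits patients into "high" (value at or above the sample median) and
#' "low" (below). For even n the median is the midpoint of the two central
#' order statistics; patients tied with the threshold are labelled high by
#' the "above or equal" rule.
#'
#' @param values named numeric vector (names are patient ids); `NA`s are
#'   left unlabelled.
#' @return a list with `labels` (character vector in `{"high", "low"}`,
#'   `NA` where the value is missing) and `threshold` (the median used).
#' @export
#' @examples
#' dichotomize(c(a = 1, b = 2, c = 3, d = 4, e = 5))$labels
dichotomize <- function(values) {
  v <- as.numeric(values)
  if (all(is.na(v))) {
    stop_icb("cannot dichotomize: all values missing",
             "icbcombo_validation_error")
  }
  if (sum(!is.na(v)) < 2L) {
    stop_icb("dichotomize requires at least two non-missing values",
             "icbcombo_validation_error")
  }
  if (any(!is.finite(v[!is.na(v)]))) {
    stop_icb("values must be finite", "icbcombo_validation_error")
  }
  thr <- median(v, na.rm = TRUE)
  labels <- ifelse(is.na(v), NA_character_,
                   ifelse(v >= thr, "high", "low"))
  names(labels) <- names(values)
  list(labels = labels, threshold = thr)
}

#' Specify a biomarker combination
#'
#' Two modes: `all_of` requires "high" status in every member biomarker of
#' the subset; `at_least_k` requires "high" status in at least `k` of the
#' four biomarkers (the full panel).
#'
#' @param mode `"all_of"` or `"at_least_k"`.
#' @param members character subset of `c("neoload", "pdl2", "cyt", "tdiv")`
#'   (mode `all_of`).
#' @param k integer in 1..4 (mode `at_least_k`).
#' @return a list of class `icb_combination_spec` with a `label` field.
#' @export
combination_spec <- function(mode = c("all_of", "at_least_k"),
                             members = NULL, k = NULL) {
  mode <- match.arg(mode)
  if (mode == "all_of") {
    if (is.null(members) || length(members) == 0L) {
      stop_icb("all_of spec needs at least one member",
               "icbcombo_validation_error")
    }
    members <- tolower(members)
    bad <- setdiff(members, BIOMARKERS)
    if (length(bad) > 0L) {
      stop_icb(sprintf("unknown biomarker(s): %s (allowed: %s)",
                       paste(bad, collapse = ", "),
                       paste(BIOMARKERS, collapse = ", ")),
               "icbcombo_validation_error")
    }
    members <- BIOMARKERS[BIOMARKERS %in% members]  # canonical order
    label <- paste(BIOMARKER_LABELS[members], collapse = "+")
    spec <- list(mode = mode, members = members, k = NULL, label = label)
  } else {
    if (is.null(k) || !k %in% 1:4) {
      stop_icb("at_least_k spec needs k in 1..4", "icbcombo_validation_error")
    }
    spec <- list(mode = mode, members = BIOMARKERS, k = as.integer(k),
                 label = sprintf(">=%d of 4", k))
  }
  structure(spec, class = "icb_combination_spec")
}

#' @export
print.icb_combination_spec <- function(x, ...) {
  cat("<combination spec>", x$label, "\n")
  invisible(x)
}

#' Enumerate all biomarker combinations
#'
#' The 15 non-empty subsets of the four biomarkers (combined with AND
#' logic) plus the "high in at least 2 of 4" and "at least 3 of 4" rules:
#' 17 specs, in deterministic order (singletons, pairs, triples, the
#' quadruple, then the k-rules).
#'
#' @return list of [combination_spec()] objects, length 17.
#' @export
enumerate_combinations <- function() {
  specs <- list()
  for (size in 1:4) {
    subsets <- combn(BIOMARKERS, size, simplify = FALSE)
    for (s in subsets) {
      specs[[length(specs) + 1L]] <- combination_spec("all_of", members = s)
    }
  }
  specs[[length(specs) + 1L]] <- combination_spec("at_least_k", k = 2L)
  specs[[length(specs) + 1L]] <- combination_spec("at_least_k", k = 3L)
  specs
}

#' Assign patients to high/low groups for a combination
#'
#' Each biomarker is dichotomized at its own median over classifiable
#' (complete-case) patients; a patient is "high" for an `all_of` spec when
#' high in every member biomarker, and for an `at_least_k` spec when high
#' in at least `k` of the four single-biomarker splits. Remaining patients
#' are "low". Patients with a missing member biomarker are unlabelled.
#'
#' @param panel data frame with `patient_id` and the biomarker columns
#'   `neoload`, `pdl2`, `cyt`, `tdiv` (only the spec's members are
#'   required).
#' @param spec a [combination_spec()].
#' @return a list of class `icb_group_assignment` with `labels` (named
#'   character vector), `thresholds` (named numeric, the medians used) and
#'   `spec`.
#' @export
assign_groups <- function(panel, spec) {
  stopifnot(inherits(spec, "icb_combination_spec"))
  assert_columns(panel, c("patient_id", spec$members), "biomarker panel")
  if (anyDuplicated(panel$patient_id)) {
    stop_icb("duplicate patient_id in panel", "icbcombo_validation_error")
  }
  splits <- lapply(spec$members, function(b) {
    dichotomize(setNames(panel[[b]], panel$patient_id))
  })
  names(splits) <- spec$members
  high_mat <- vapply(splits, function(s) s$labels == "high",
                     logical(nrow(panel)))
  if (is.null(dim(high_mat))) high_mat <- matrix(high_mat, nrow = 1L)
  if (spec$mode == "all_of") {
    high <- apply(high_mat, 1L, function(r) {
      if (any(is.na(r))) NA else all(r)
    })
  } else {
    high <- apply(high_mat, 1L, function(r) {
      if (any(is.na(r))) NA else sum(r) >= spec$k
    })
  }
  labels <- setNames(ifelse(is.na(high), NA_character_,
                            ifelse(high, "high", "low")),
                     panel$patient_id)
  structure(list(labels = labels,
                 thresholds = vapply(splits, `[[`, numeric(1), "threshold"),
                 spec = spec),
            class = "icb_group_assignment")
}

#' @export
print.icb_group_assignment <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("high", "low")))
  cat(sprintf("<group assignment> %s: %d high / %d low\n",
              x$spec$label, tab[["high"]], tab[["low"]]))
  invisible(x)
}
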