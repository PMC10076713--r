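# Transcriptome-derived biomarkers: gene expression lookup with probe
# aggregation, cytolytic activity (CYT), CDR3 Shannon entropy (Tdiv) and
# the two-group Wilcoxon comparison used throughout.

# canonical PD-L2 symbol and the spellings accepted for it
PDL2_CANONICAL <- "PDCD1LG2"
PDL2_ALIASES <- c("PDCD1LG2", "PD-L2", "PDL2", "PDCDLG2", "PDCD1L2")

resolve_gene_alias <- function(gene_symbol) {
  if (toupper(gene_symbol) %in% toupper(PDL2_ALIASES)) PDL2_CANONICAL
  else gene_symbol
}

#' Per-patient expression of one gene
#'
#' For a gene-level matrix, returns the gene's row. For a probe-level
#' matrix (e.g. expression array), returns the unweighted arithmetic mean
#' over all probes mapping to the gene. PD-L2 spelling variants
#' (PDCD1LG2, PD-L2, PDCDLG2, PDCD1L2) resolve to one canonical symbol.
#'
#' @param matrix numeric matrix, features (genes or probes) x patients,
#'   with feature row names and patient column names.
#' @param gene_symbol gene to look up.
#' @param probe_map optional data frame with columns `probe`, `gene`
#'   mapping probe ids to gene symbols; its presence marks the matrix as
#'   probe-level.
#' @return named numeric vector, one value per patient.
#' @export
#' @examples
#' m <- matrix(c(4, 6), 2, 1, dimnames = list(c("p1", "p2"), "pt1"))
#' pm <- data.frame(probe = c("p1", "p2"), gene = "PDCD1LG2")
#' gene_expression(m, "PD-L2", probe_map = pm)   # 5
gene_expression <- function(matrix, gene_symbol, probe_map = NULL) {
  gene_symbol <- resolve_gene_alias(gene_symbol)
  if (is.null(probe_map)) {
    if (!gene_symbol %in% rownames(matrix)) {
      near <- agrep(gene_symbol, rownames(matrix), max.distance = 0.2,
                    ignore.case = TRUE, value = TRUE)
      stop_icb(sprintf("gene '%s' not found in expression matrix%s",
                       gene_symbol,
                       if (length(near)) paste0(" (near misses: ",
                         paste(head(near, 5), collapse = ", "), ")") else ""),
               "icbcombo_lookup_error")
    }
    return(matrix[gene_symbol, ])
  }
  assert_columns(probe_map, c("probe", "gene"), "probe map")
  probes <- probe_map$probe[resolve_alias_vec(probe_map$gene) == gene_symbol]
  probes <- intersect(probes, rownames(matrix))
  if (length(probes) == 0L) {
    stop_icb(sprintf("no probes map to gene '%s'", gene_symbol),
             "icbcombo_lookup_error")
  }
  colMeans(matrix[probes, , drop = FALSE])
}

resolve_alias_vec <- function(x) {
  vapply(x, resolve_gene_alias, character(1), USE.NAMES = FALSE)
}

#' Cytolytic activity (CYT)
#'
#' The geometric mean of GZMA (granzyme A) and PRF1 (perforin) expression,
#' per patient: `sqrt(GZMA * PRF1)`. Zero expression values are replaced
#' by a small pseudocount (default 0.01) before the product so the
#' geometric mean stays finite; strictly positive values are used as-is,
#' preserving the identity CYT(x, x) = x.
#'
#' @param matrix features x patients expression matrix (TPM or normalized
#'   array intensity).
#' @param probe_map optional probe-to-gene map (see [gene_expression()]).
#' @param pseudocount value substituted for zero expression.
#' @return named numeric vector of CYT per patient.
#' @export
#' @examples
#' m <- matrix(c(4, 9), 2, 1, dimnames = list(c("GZMA", "PRF1"), "pt1"))
#' cyt(m)   # 6
cyt <- function(matrix, probe_map = NULL, pseudocount = 0.01) {
  g <- gene_expression(matrix, "GZMA", probe_map)
  p <- gene_expression(matrix, "PRF1", probe_map)
  if (any(g < 0, na.rm = TRUE) || any(p < 0, na.rm = TRUE)) {
    stop_icb("negative expression values are not allowed",
             "icbcombo_validation_error")
  }
  g[!is.na(g) & g == 0] <- pseudocount
  p[!is.na(p) & p == 0] <- pseudocount
  sqrt(g * p)
}

#' Shannon entropy of a clone repertoire
#'
#' T-cell diversity index: `H = -sum(p_i * log(p_i))` over clone
#' frequencies `p_i = count_i / sum(counts)`. Duplicate CDR3 sequences are
#' merged by summing their counts before computing frequencies. Natural
#' logarithm by default; the base only rescales H and cannot change a
#' median dichotomization. Clone counts may be fractional (read-assignment
#' software reports fractional counts for ambiguously assigned reads).
#'
#' @param counts positive numeric clone counts, or a data frame with
#'   columns `cdr3` (or `aaSeqCDR3`) and `count` (or `cloneCount`).
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return non-negative scalar; 0 for a monoclonal (or empty) repertoire.
#' @export
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))   # log(4)
#' shannon_entropy(c(1, 1, 2))      # 1.0397
shannon_entropy <- function(counts, base = exp(1)) {
  if (is.data.frame(counts)) {
    seq_col <- intersect(c("cdr3", "aaSeqCDR3"), names(counts))[1]
    cnt_col <- intersect(c("count", "cloneCount"), names(counts))[1]
    if (is.na(seq_col) || is.na(cnt_col)) {
      stop_icb("clone table needs columns cdr3/aaSeqCDR3 and count/cloneCount",
               "icbcombo_schema_error")
    }
    counts <- tapply(counts[[cnt_col]], counts[[seq_col]], sum)
  }
  counts <- as.numeric(counts)
  if (length(counts) == 0L) {
    warning("empty clone table; entropy defined as 0")
    return(0)
  }
  if (any(is.na(counts)) || any(counts <= 0)) {
    stop_icb("clone counts must be positive", "icbcombo_validation_error")
  }
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(base)
}

#' Two-group Wilcoxon rank-sum test (normal approximation)
#'
#' Unpaired Mann-Whitney/Wilcoxon rank-sum test with normal approximation,
#' tie-corrected variance and 0.5 continuity correction -- the comparison
#' used for all between-group biomarker contrasts. When every value is
#' identical across both groups the test is degenerate and p = 1.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `statistic` (the Mann-Whitney U for `group_a`) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_icb("both groups must be non-empty", "icbcombo_validation_error")
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p_value = 1))
  }
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)
  )
  p <- res$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), p_value = min(p, 1))
}

#' Assemble the per-patient signature panel
#'
#' Computes CYT, PD-L2 expression and T-cell diversity (Shannon entropy)
#' for every patient present in the expression matrix. Patients missing a
#' clone table get `NA` diversity and are flagged, never silently imputed.
#'
#' @param matrix features x patients expression matrix.
#' @param clones_by_patient named list of clone tables (one per patient;
#'   data frames accepted by [shannon_entropy()]).
#' @param probe_map optional probe-to-gene map.
#' @param pdl2_symbol symbol used for the PD-L2 lookup.
#' @param entropy_base logarithm base for the diversity index.
#' @param pseudocount CYT pseudocount for zero expression.
#' @return data frame with columns `patient_id`, `cyt`, `pdl2`, `tdiv`,
#'   `complete`.
#' @export
signature_panel <- function(matrix, clones_by_patient, probe_map = NULL,
                            pdl2_symbol = "PDCD1LG2",
                            entropy_base = exp(1), pseudocount = 0.01) {
  patients <- colnames(matrix)
  if (is.null(patients) || length(patients) == 0L) {
    stop_icb("expression matrix must have patient column names",
             "icbcombo_validation_error")
  }
  if (length(intersect(patients, names(clones_by_patient))) == 0L &&
      length(clones_by_patient) > 0L) {
    stop_icb("no overlapping patients between expression and clone tables",
             "icbcombo_validation_error")
  }
  cyt_v <- cyt(matrix, probe_map, pseudocount)
  pdl2_v <- gene_expression(matrix, pdl2_symbol, probe_map)
  tdiv_v <- vapply(patients, function(p) {
    tab <- clones_by_patient[[p]]
    if (is.null(tab)) return(NA_real_)
    shannon_entropy(tab, base = entropy_base)
  }, numeric(1))
  out <- data.frame(patient_id = patients,
                    cyt = unname(cyt_v[patients]),
                    pdl2 = unname(pdl2_v[patients]),
                    tdiv = unname(tdiv_v),
                    stringsAsFactors = FALSE)
  out$complete <- complete.cases(out[, c("cyt", "pdl2", "tdiv")])
  rownames(out) <- NULL
  out
}
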