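# Neoepitope arm: consequence classification, mutant peptide extraction,
# TMB counts and the filtered neoepitope load.

NONSYNONYMOUS_CONSEQUENCES <- c("missense", "inframe_insertion",
                                "inframe_deletion", "frameshift")

#' Construct a transcript model
#'
#' A transcript model carries the coding sequence (CDS) and its protein
#' translation for one transcript. The CDS must have length divisible by
#' three and end at a stop codon; the stored protein excludes the stop.
#'
#' @param transcript_id transcript identifier.
#' @param gene gene symbol.
#' @param cds_sequence coding nucleotide sequence (A/C/G/T), including the
#'   terminal stop codon.
#' @return a list of class `icb_transcript`.
#' @export
#' @examples
#' tx <- transcript_model("tx1", "GENE1", "ATGGCTGCTTAA")
#' tx$protein   # "MAA"
transcript_model <- function(transcript_id, gene, cds_sequence) {
  cds_sequence <- toupper(gsub("\\s", "", cds_sequence))
  if (nchar(cds_sequence) %% 3 != 0) {
    stop_icb("CDS length must be divisible by 3", "icbcombo_validation_error")
  }
  aa <- translate_cds(cds_sequence, to_first_stop = FALSE)
  if (!endsWith(aa, "*")) {
    stop_icb("CDS must end at a stop codon", "icbcombo_validation_error")
  }
  protein <- sub("\\*.*$", "", aa)
  structure(list(transcript_id = transcript_id, gene = gene,
                 cds = cds_sequence, protein = protein),
            class = "icb_transcript")
}

# translate a nucleotide string; trailing partial codon is dropped
translate_cds <- function(cds, to_first_stop = TRUE) {
  n <- nchar(cds)
  n3 <- (n %/% 3L) * 3L
  if (n3 == 0L) return("")
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n3)),
                          if.fuzzy.codon = "X")
  ))
  if (to_first_stop) sub("\\*.*$", "", aa) else aa
}

#' Construct a somatic variant
#'
#' Variants are represented in CDS coordinates: `cds_pos` is the 1-based
#' position of the first reference base within the coding sequence, and
#' `ref`/`alt` are coding-strand allele strings in VCF-style anchored
#' notation (e.g. `ref = "AT", alt = "A"` for a 1-bp deletion).
#'
#' @param transcript_id transcript the variant maps to.
#' @param cds_pos 1-based position within the CDS.
#' @param ref,alt reference and alternate allele strings.
#' @param gene gene symbol (optional; taken from the transcript otherwise).
#' @param chrom,pos genomic coordinates (optional provenance).
#' @param id variant identifier; defaults to
#'   `"<transcript>:<cds_pos>:<ref>><alt>"`.
#' @return a list of class `icb_variant`.
#' @export
somatic_variant <- function(transcript_id, cds_pos, ref, alt, gene = NA,
                            chrom = NA, pos = NA, id = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) {
    stop_icb("ref and alt alleles must differ", "icbcombo_validation_error")
  }
  if (cds_pos < 1) {
    stop_icb("cds_pos must be >= 1", "icbcombo_validation_error")
  }
  structure(list(
    transcript_id = transcript_id, cds_pos = as.integer(cds_pos),
    ref = ref, alt = alt, gene = gene, chrom = chrom, pos = pos,
    id = id %||% sprintf("%s:%d:%s>%s", transcript_id, cds_pos, ref, alt)
  ), class = "icb_variant")
}

# apply a variant to a CDS string; NULL when the reference does not match
apply_variant <- function(variant, cds) {
  p <- variant$cds_pos
  end <- p + nchar(variant$ref) - 1L
  if (end > nchar(cds)) return(NULL)
  if (substr(cds, p, end) != variant$ref) {
    stop_icb(sprintf("reference allele mismatch at CDS position %d of %s",
                     p, variant$transcript_id),
             "icbcombo_validation_error")
  }
  paste0(substr(cds, 1L, p - 1L), variant$alt,
         substr(cds, end + 1L, nchar(cds)))
}

#' Classify the coding consequence of a somatic variant
#'
#' Single-nucleotide (and other length-preserving) variants are classified
#' by comparing the translated mutant protein with the reference protein:
#' an amino-acid change is `missense`, no change is `synonymous`.
#' Length-changing variants are in-frame insertions/deletions when the
#' length difference is a multiple of three, otherwise `frameshift`.
#' Variants outside the CDS, or SNVs that create or destroy a stop codon,
#' are classified `other` (no peptides are extracted from them).
#'
#' @param variant an [somatic_variant()].
#' @param transcript the matching [transcript_model()].
#' @return one of `"missense"`, `"synonymous"`, `"inframe_insertion"`,
#'   `"inframe_deletion"`, `"frameshift"`, `"other"`.
#' @export
classify_consequence <- function(variant, transcript) {
  if (variant$cds_pos > nchar(transcript$cds)) return("other")
  mut_cds <- apply_variant(variant, transcript$cds)
  if (is.null(mut_cds)) return("other")
  d <- nchar(variant$alt) - nchar(variant$ref)
  if (d %% 3L != 0L) return("frameshift")
  if (d > 0L) return("inframe_insertion")
  if (d < 0L) return("inframe_deletion")
  # length-preserving: compare translations over the reference register
  mut_aa <- translate_cds(mut_cds, to_first_stop = FALSE)
  ref_aa <- paste0(transcript$protein, "*")
  if (identical(mut_aa, ref_aa)) return("synonymous")
  # stop gained/lost: protein truncated or extended, outside scope
  mut_prot <- sub("\\*.*$", "", mut_aa)
  if (nchar(mut_prot) != nchar(transcript$protein)) return("other")
  "missense"
}

# longest common prefix / suffix lengths of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}
lcs_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Extract mutant peptides from a somatic variant
#'
#' Emits every full-length window of each requested length that overlaps at
#' least one altered residue of the mutant protein. For missense and
#' in-frame variants the altered region is the span between the longest
#' common prefix and suffix of the mutant and reference proteins, and each
#' peptide is paired with the reference-register window at the same
#' coordinates (when one exists and differs from the mutant peptide). For
#' frameshifts the mutant frame is translated from the first divergent
#' residue to the first stop codon (or CDS end if none) and every window
#' containing novel sequence is emitted with no reference counterpart.
#' Windows truncated by the protein ends are omitted.
#'
#' Identical peptide strings arising from different windows of the same
#' mutation are reported once.
#'
#' @param variant an [somatic_variant()].
#' @param transcript the matching [transcript_model()].
#' @param lengths integer vector of peptide lengths (default 8--11).
#' @return a data frame with columns `peptide`, `normal_peptide` (NA for
#'   frameshift-derived novel sequence), `gene`, `mutation_id`,
#'   `consequence`, `length`.
#' @export
extract_mutant_peptides <- function(variant, transcript,
                                    lengths = c(8L, 9L, 10L, 11L)) {
  cons <- classify_consequence(variant, transcript)
  empty <- data.frame(peptide = character(), normal_peptide = character(),
                      gene = character(), mutation_id = character(),
                      consequence = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (!cons %in% NONSYNONYMOUS_CONSEQUENCES) return(empty)

  mut_cds <- apply_variant(variant, transcript$cds)
  mut_prot <- translate_cds(mut_cds, to_first_stop = TRUE)
  ref_prot <- transcript$protein
  n_mut <- nchar(mut_prot)
  if (n_mut == 0L) return(empty)

  pfx <- lcp_len(mut_prot, ref_prot)
  if (cons == "frameshift") {
    if (pfx >= n_mut) return(empty)  # stop before any novel residue
    alt_lo <- pfx + 1L
    alt_hi <- n_mut
  } else {
    sfx <- lcs_len(mut_prot, ref_prot, max_len = min(n_mut, nchar(ref_prot)) - pfx)
    alt_lo <- pfx + 1L
    alt_hi <- n_mut - sfx
    if (alt_hi < alt_lo) return(empty)  # protein unchanged
  }

  gene <- if (is.na(variant$gene) || is.null(variant$gene))
    transcript$gene else variant$gene
  same_register <- cons == "missense"

  rows <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    if (L > n_mut) next
    s_lo <- max(1L, alt_lo - L + 1L)
    s_hi <- min(alt_hi, n_mut - L + 1L)
    if (s_hi < s_lo) next
    for (s in s_lo:s_hi) {
      pep <- substr(mut_prot, s, s + L - 1L)
      np <- NA_character_
      if (cons %in% c("missense", "inframe_insertion", "inframe_deletion")) {
        if (s + L - 1L <= nchar(ref_prot)) np <- substr(ref_prot, s, s + L - 1L)
        if (!is.na(np) && np == pep) next  # indel window identical in reference
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, normal_peptide = np, gene = gene,
        mutation_id = variant$id, consequence = cons, length = L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[!duplicated(out$peptide), , drop = FALSE]
}

#' Total tumor mutational burden
#'
#' Counts every filter-passed variant entry, regardless of consequence.
#'
#' @param variants a data frame with one row per variant, or a list of
#'   variants.
#' @return integer count.
#' @export
tmb_total <- function(variants) {
  if (is.data.frame(variants)) nrow(variants) else length(variants)
}

#' Non-synonymous tumor mutational burden
#'
#' Counts variants whose consequence is missense, in-frame insertion,
#' in-frame deletion or frameshift.
#'
#' @param variants a data frame with a `consequence` column, or a character
#'   vector of consequences.
#' @return integer count.
#' @export
tmb_nonsynonymous <- function(variants) {
  cons <- if (is.data.frame(variants)) {
    assert_columns(variants, "consequence")
    variants$consequence
  } else {
    as.character(variants)
  }
  sum(cons %in% NONSYNONYMOUS_CONSEQUENCES)
}

#' Neoepitope selection filter
#'
#' The selection thresholds applied to candidate mutant peptides: gene
#' expression strictly above `tpm_min` (default 0.1 TPM) and predicted MHC
#' eluted-ligand percentile rank strictly below `rank_max` (default 2).
#'
#' @param tpm_min exclusive lower bound on gene-of-origin expression (TPM).
#' @param rank_max exclusive upper bound on the EL percentile rank.
#' @param lengths peptide lengths considered.
#' @return a list of class `icb_neoepitope_filter`.
#' @export
neoepitope_filter <- function(tpm_min = 0.1, rank_max = 2,
                              lengths = c(8L, 9L, 10L, 11L)) {
  stopifnot(tpm_min >= 0, rank_max > 0, rank_max <= 100)
  structure(list(tpm_min = tpm_min, rank_max = rank_max,
                 lengths = as.integer(lengths)),
            class = "icb_neoepitope_filter")
}

#' Neoepitope load
#'
#' Counts candidate peptide--HLA pairs passing the expression and binding
#' filters: `expression_tpm > tpm_min` and `rank < rank_max` (both strict).
#' The counting unit is distinct (mutation, peptide, HLA allele) pairs by
#' default; `unit = "peptides"` instead counts distinct peptides with at
#' least one passing allele. Identical peptides from different mutations
#' count per mutation; identical peptides from the same mutation count
#' once.
#'
#' @param peptides a long-format data frame with columns `peptide`,
#'   `allele`, `rank`, `expression_tpm` and optionally `mutation_id`.
#' @param filter an [neoepitope_filter()].
#' @param unit `"pairs"` (default) or `"peptides"`.
#' @return integer count.
#' @export
#' @examples
#' tab <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC"),
#'                   allele = "HLA-A*02:01", rank = c(0.5, 3),
#'                   expression_tpm = c(5, 5))
#' neoepitope_load(tab)   # 1
neoepitope_load <- function(peptides, filter = neoepitope_filter(),
                            unit = c("pairs", "peptides")) {
  unit <- match.arg(unit)
  if (is.null(peptides) || nrow(peptides) == 0L) return(0L)
  assert_columns(peptides, c("peptide", "allele", "rank", "expression_tpm"),
                 "peptide table")
  no_rank <- is.na(peptides$rank)
  if (any(no_rank)) {
    dropped <- unique(peptides$peptide[no_rank])
    warning(sprintf("%d peptide(s) without a binding rank were excluded",
                    length(dropped)))
    peptides <- peptides[!no_rank, , drop = FALSE]
    if (nrow(peptides) == 0L) return(0L)
  }
  pass <- peptides$expression_tpm > filter$tpm_min &
    peptides$rank < filter$rank_max
  hits <- peptides[pass, , drop = FALSE]
  if (nrow(hits) == 0L) return(0L)
  mut <- if ("mutation_id" %in% names(hits)) hits$mutation_id else ""
  key <- if (unit == "pairs") {
    paste(mut, hits$peptide, hits$allele, sep = "\r")
  } else {
    paste(mut, hits$peptide, sep = "\r")
  }
  length(unique(key))
}

#' File-backed binding-rank provider
#'
#' Reads a TSV of predicted eluted-ligand percentile ranks (columns
#' `peptide`, `allele`, `rank`) and returns a provider function that, given
#' peptides and alleles, returns the matching long-format rank table.
#' Pairs absent from the file get `NA` ranks.
#'
#' @param path path to the rank TSV.
#' @return a function `(peptides, alleles) -> data.frame(peptide, allele,
#'   rank)`.
#' @export
rank_provider_file <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(tab, c("peptide", "allele", "rank"), "rank table")
  tab$key <- paste(tab$peptide, tab$allele, sep = "\r")
  function(peptides, alleles) {
    grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                        stringsAsFactors = FALSE)
    idx <- match(paste(grid$peptide, grid$allele, sep = "\r"), tab$key)
    grid$rank <- tab$rank[idx]
    grid
  }
}

#' Deterministic mock binding-rank provider
#'
#' Produces pseudo-random but fully deterministic percentile ranks in
#' (0, 100) from an arithmetic hash of (peptide, allele, seed). Used in
#' tests and simulations so that no external binding predictor is needed.
#'
#' @param seed integer seed folded into the hash.
#' @return a function `(peptides, alleles) -> data.frame(peptide, allele,
#'   rank)`.
#' @export
rank_provider_mock <- function(seed = 1L) {
  force(seed)
  hash1 <- function(s) {
    h <- (as.double(seed) + 7919) %% 2147483647
    for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
    h
  }
  function(peptides, alleles) {
    grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                        stringsAsFactors = FALSE)
    h <- vapply(paste0(grid$peptide, "|", grid$allele), hash1, numeric(1))
    grid$rank <- ((h %% 1e6) + 0.5) / 1e6 * 100
    rownames(grid) <- NULL
    grid
  }
}

#' Attach binding ranks and expression to extracted peptides
#'
#' Expands a peptide table to long format over the patient's HLA alleles,
#' querying a rank provider for each (peptide, allele) pair and joining
#' gene-of-origin expression.
#'
#' @param peptides output of [extract_mutant_peptides()] (rows from one or
#'   more variants).
#' @param alleles character vector of the patient's HLA class I alleles.
#' @param provider a rank provider from [rank_provider_file()] or
#'   [rank_provider_mock()].
#' @param expression named numeric vector of gene expression (TPM), names
#'   are gene symbols.
#' @return long-format data frame ready for [neoepitope_load()].
#' @export
attach_ranks <- function(peptides, alleles, provider, expression) {
  if (nrow(peptides) == 0L) {
    return(data.frame(peptide = character(), allele = character(),
                      rank = numeric(), expression_tpm = numeric(),
                      mutation_id = character(), stringsAsFactors = FALSE))
  }
  ranks <- provider(peptides$peptide, alleles)
  out <- merge(peptides, ranks, by = "peptide")
  out$expression_tpm <- unname(expression[out$gene])
  out$expression_tpm[is.na(out$expression_tpm)] <- 0
  out
}
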