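# Readers for the molecular input formats: expression TSV, probe maps,
# clone tables, CDS FASTA (via Biostrings) and annotated somatic-variant
# VCFs (via vcfR).

#' Read a features-by-patients expression matrix
#'
#' TSV with the feature identifier (gene symbol or probe id) in the first
#' column and one column per patient.
#'
#' @param path TSV path.
#' @return numeric matrix with feature row names and patient column names.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_icb("expression table needs a feature column plus >=1 patient",
             "icbcombo_schema_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop_icb("expression values must be numeric", "icbcombo_schema_error")
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop_icb("expression values must be non-negative",
             "icbcombo_validation_error")
  }
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a probe-to-gene map
#'
#' @param path TSV with columns `probe` and `gene`.
#' @return data frame.
#' @export
read_probe_map <- function(path) {
  pm <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(pm, c("probe", "gene"), "probe map")
  pm
}

#' Read a CDR3 clone table
#'
#' Accepts a MiXCR-style export (columns `cloneCount`, `aaSeqCDR3`) or a
#' generic table with `count` and `cdr3` columns.
#'
#' @param path TSV path.
#' @return data frame with columns `cdr3`, `count`.
#' @export
read_clone_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  seq_col <- intersect(c("aaSeqCDR3", "cdr3"), names(tab))[1]
  cnt_col <- intersect(c("cloneCount", "count"), names(tab))[1]
  if (is.na(seq_col) || is.na(cnt_col)) {
    stop_icb(sprintf("clone table %s needs cdr3/aaSeqCDR3 and count/cloneCount columns",
                     path), "icbcombo_schema_error")
  }
  data.frame(cdr3 = as.character(tab[[seq_col]]),
             count = as.numeric(tab[[cnt_col]]), stringsAsFactors = FALSE)
}

#' Read transcript models from a CDS FASTA
#'
#' Header format `>transcript_id gene=SYMBOL`; each record is a complete
#' coding sequence ending at a stop codon.
#'
#' @param path FASTA path.
#' @return named list of [transcript_model()] objects keyed by transcript
#'   id.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    txid <- strsplit(header, "\\s+")[[1]][1]
    gene <- sub(".*gene=([^ ]+).*", "\\1", header)
    if (gene == header) gene <- txid
    out[[txid]] <- transcript_model(txid, gene, as.character(seqs[[i]]))
  }
  out
}

#' Read annotated somatic variants from a VCF
#'
#' Expects VCF 4.x. CDS-level annotation is taken from the INFO keys
#' `TRANSCRIPT`, `CDSPOS` and `GENE`, or alternatively from a sidecar
#' annotation TSV with columns `id`, `transcript_id`, `cds_pos`, `gene`
#' keyed by the VCF ID field.
#'
#' @param path VCF path.
#' @param annotations optional sidecar annotation data frame or TSV path.
#' @return list of [somatic_variant()] objects.
#' @export
read_variants_vcf <- function(path, annotations = NULL) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix)) return(list())
  if (is.null(dim(fix))) {          # single-record VCF: named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) return(list())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!is.null(annotations) && !is.data.frame(annotations)) {
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  }
  info_field <- function(key) {
    unname(vcfR::extract.info(vcf, element = key))
  }
  tx <- info_field("TRANSCRIPT")
  cp <- suppressWarnings(as.integer(info_field("CDSPOS")))
  gn <- info_field("GENE")
  variants <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    txid <- tx[i]; cds_pos <- cp[i]; gene <- gn[i]
    if ((is.null(txid) || is.na(txid)) && !is.null(annotations)) {
      assert_columns(annotations, c("id", "transcript_id", "cds_pos"),
                     "variant annotations")
      j <- match(fix$ID[i], annotations$id)
      if (!is.na(j)) {
        txid <- annotations$transcript_id[j]
        cds_pos <- annotations$cds_pos[j]
        gene <- if ("gene" %in% names(annotations))
          annotations$gene[j] else NA
      }
    }
    if (is.null(txid) || is.na(txid) || is.na(cds_pos)) {
      stop_icb(sprintf(
        "variant %s:%s lacks TRANSCRIPT/CDSPOS annotation (INFO or sidecar)",
        fix$CHROM[i], fix$POS[i]), "icbcombo_schema_error")
    }
    variants[[i]] <- somatic_variant(
      transcript_id = txid, cds_pos = as.integer(cds_pos),
      ref = fix$REF[i], alt = fix$ALT[i],
      gene = if (is.null(gene)) NA else gene,
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      id = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NULL else fix$ID[i])
  }
  variants
}

#' Compute one patient's neoepitope load from raw inputs
#'
#' Runs the full neoantigen arm for a single patient: peptide extraction
#' from each variant, expansion over the patient's HLA alleles with
#' binding ranks from the provider, expression join, and the filtered
#' count.
#'
#' @param variants list of [somatic_variant()] (e.g. from
#'   [read_variants_vcf()]).
#' @param transcripts named list of [transcript_model()] objects.
#' @param alleles the patient's HLA class I alleles.
#' @param provider binding-rank provider function.
#' @param expression named numeric vector of gene TPM for this patient.
#' @param filter an [neoepitope_filter()].
#' @param unit counting unit passed to [neoepitope_load()].
#' @return integer neoepitope load.
#' @export
compute_neoload <- function(variants, transcripts, alleles, provider,
                            expression, filter = neoepitope_filter(),
                            unit = "pairs") {
  if (length(variants) == 0L) return(0L)
  pep_list <- lapply(variants, function(v) {
    tx <- transcripts[[v$transcript_id]]
    if (is.null(tx)) {
      stop_icb(sprintf("transcript %s not found in CDS FASTA",
                       v$transcript_id), "icbcombo_lookup_error")
    }
    extract_mutant_peptides(v, tx, lengths = filter$lengths)
  })
  peps <- do.call(rbind, pep_list)
  if (is.null(peps) || nrow(peps) == 0L) return(0L)
  long <- attach_ranks(peps, alleles, provider, expression)
  neoepitope_load(long, filter = filter, unit = unit)
}
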