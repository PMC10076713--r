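# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# independent codon table for building CDS fixtures (one codon per aa)
ORACLE_CODONS <- c(A = "GCA", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
                   G = "GGA", H = "CAC", I = "ATC", K = "AAG", L = "CTC",
                   M = "ATG", N = "AAC", P = "CCA", Q = "CAG", R = "AGA",
                   S = "AGC", T = "ACA", V = "GTA", W = "TGG", Y = "TAC")

oracle_cds <- function(protein) {
  paste0(paste(ORACLE_CODONS[strsplit(protein, "")[[1]]], collapse = ""),
         "TGA")
}

# build a missense fixture: reference protein with Ala at position p,
# SNV turning that codon (GCA) into GTA (Val)
make_missense_fixture <- function(n_aa, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prot <- paste(sample(AA20, n_aa, replace = TRUE), collapse = "")
  substr(prot, p, p) <- "A"
  cds <- oracle_cds(prot)
  tx <- transcript_model(sprintf("tx_N%d_p%d", n_aa, p), "GENE", cds)
  var <- somatic_variant(tx$transcript_id, cds_pos = 3L * (p - 1L) + 2L,
                         ref = "C", alt = "T")
  mut_prot <- prot
  substr(mut_prot, p, p) <- "V"
  list(tx = tx, var = var, ref_prot = prot, mut_prot = mut_prot, pos = p)
}

# brute-force peptide oracle: all unique length-L substrings of the mutant
# protein whose window covers at least one altered position
oracle_peptides <- function(mut_prot, altered, L) {
  n <- nchar(mut_prot)
  if (L > n) return(character(0))
  starts <- seq_len(n - L + 1L)
  keep <- vapply(starts, function(s) {
    any(altered >= s & altered <= s + L - 1L)
  }, logical(1))
  unique(vapply(starts[keep], function(s) substr(mut_prot, s, s + L - 1L),
                character(1)))
}

# exact two-sided Mann-Whitney p-value by permutation enumeration
oracle_wilcox_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a); n2 <- length(b)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# grid/optimize maximization of the Cox partial likelihood (no ties),
# written directly from the likelihood definition
oracle_cox_beta <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  loglik <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  stats::optimize(loglik, interval = c(-15, 15), maximum = TRUE,
                  tol = 1e-9)$maximum
}

# hand-computed two-group log-rank chi-square (observed minus expected
# over distinct event times, hypergeometric variance)
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# random long-format peptide table for filter monotonicity checks
random_peptide_table <- function(n) {
  data.frame(
    peptide = vapply(seq_len(n), function(i)
      paste(sample(AA20, 9, replace = TRUE), collapse = ""), character(1)),
    allele = sample(c("HLA-A*02:01", "HLA-B*07:02"), n, replace = TRUE),
    rank = stats::runif(n, 0, 5),
    expression_tpm = stats::runif(n, 0, 1),
    mutation_id = sample(sprintf("m%d", 1:5), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

BIOMARKERS_FOR_TEST <- c("neoload", "pdl2", "cyt", "tdiv")

table1_path <- function() {
  system.file("extdata", "clinical_table1.tsv", package = "icbcombo")
}
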