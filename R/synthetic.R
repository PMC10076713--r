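# Synthetic study generator: a latent-immunogenicity cohort model plus a
# constructive inverse that emits molecular input files (variants,
# transcripts, expression, binding ranks, clone tables) which reproduce
# each patient's target biomarker values when run through the real
# pipeline.

DIAGNOSIS_POOL <- c("BLCA", "BRCA", "CCA-IG", "CDC-K", "CESC", "COAD",
                    "LIHC", "OV", "PAAD", "READ", "SKCN", "UC-U")
REGIMEN_POOL <- c(
  "Atezolizumab", "Atezolizumab + Cergutuzumab Amunaleukin",
  "Atezolizumab + Selicrelumab", "Atezolizumab + Cibisatamab",
  "Atezolizumab + BET inhibitor", "Pembrolizumab", "Nivolumab",
  "Ipilimumab + Nivolumab", "Nivolumab + Relatlimab",
  "Chemotherapy + Pembrolizumab")
BIOPSY_POOL <- c("Liver", "Lung", "Lymph node", "Peritoneum",
                 "Primary tumor", "Kidney", "Subcutaneous/Cutaneous",
                 "Subcutaneous", "Other")

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate a small basket-trial cohort: 29 patients, four
#' positively inter-correlated biomarkers driven by one latent
#' immunogenicity factor, a Pearson correlation of 0.744 between CYT and
#' T-cell diversity, a small fraction of microsatellite-instable (MSI)
#' hypermutator outliers with very high mutation load but low immune
#' signatures, right-censored exponential survival whose hazard is
#' multiplied by `true_hr_combined_high` for patients "high" in the
#' designated combination, and RECIST labels drawn with benefit
#' probability increasing in the latent factor.
#'
#' @param n_patients cohort size (>= 4).
#' @param seed master seed; per-stage substreams are derived from it.
#' @param target_corr_cyt_tdiv target Pearson correlation between CYT and
#'   Tdiv; the shared latent loading is `sqrt` of it.
#' @param latent_effect optional explicit latent loading in (0, 1);
#'   overrides the loading derived from `target_corr_cyt_tdiv`.
#' @param true_hr_combined_high true hazard ratio (high vs low) for the
#'   designated combination.
#' @param combined_members biomarkers whose `all_of` combination carries
#'   the survival effect.
#' @param censoring_rate target fraction of censored observations for the
#'   overall-survival endpoint.
#' @param baseline_hazard death hazard (per month) in the low group.
#' @param progression_hazard additional progression hazard (per month);
#'   the PFS event is the first of progression and death.
#' @param cyt_mean,cyt_sd,pdl2_mean,pdl2_sd,tdiv_mean,tdiv_sd location and
#'   scale of the three continuous biomarkers (positive-valued after a
#'   small floor).
#' @param pdl2_loading latent loading of PD-L2.
#' @param neoload_log_mean,neoload_log_slope log-scale intercept and slope
#'   of the negative-binomial neoepitope load on the latent factor.
#' @param neoload_dispersion negative-binomial size parameter.
#' @param msi_outlier_fraction fraction of MSI hypermutator patients.
#' @param msi_neoload_mult multiplier on the expected mutation load of MSI
#'   patients.
#' @param msi_z_shift shift applied to the latent factor of MSI patients
#'   when drawing their immune signatures (negative = low signatures).
#' @param recist_effect logit slope of benefit probability on the latent
#'   factor.
#' @param benefit_base_rate marginal probability of non-progressive
#'   disease.
#' @return a list of class `icb_synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 29L, seed = 1L,
                             target_corr_cyt_tdiv = 0.744,
                             latent_effect = NULL,
                             true_hr_combined_high = 0.25,
                             combined_members = c("neoload", "pdl2", "cyt"),
                             censoring_rate = 0.35,
                             baseline_hazard = 0.06,
                             progression_hazard = 0.15,
                             cyt_mean = 6, cyt_sd = 2,
                             pdl2_mean = 5, pdl2_sd = 1.5,
                             tdiv_mean = 4, tdiv_sd = 1,
                             pdl2_loading = 0.7,
                             neoload_log_mean = log(50),
                             neoload_log_slope = 0.8,
                             neoload_dispersion = 1.3,
                             msi_outlier_fraction = 2 / 29,
                             msi_neoload_mult = 25,
                             msi_z_shift = -1.5,
                             recist_effect = 1.5,
                             benefit_base_rate = 11 / 29) {
  if (n_patients < 4L) {
    stop_icb("n_patients must be at least 4", "icbcombo_validation_error")
  }
  if (abs(target_corr_cyt_tdiv) > 0.99) {
    stop_icb("infeasible correlation target (|r| > 0.99)",
             "icbcombo_validation_error")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop_icb("censoring_rate must be in [0, 1)", "icbcombo_validation_error")
  }
  stopifnot(true_hr_combined_high > 0, baseline_hazard > 0,
            msi_outlier_fraction >= 0, msi_outlier_fraction < 1)
  lambda <- latent_effect %||% sqrt(abs(target_corr_cyt_tdiv))
  if (lambda < 0 || lambda >= 1) {
    stop_icb("latent_effect must lie in [0, 1)", "icbcombo_validation_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    target_corr_cyt_tdiv = target_corr_cyt_tdiv, latent_effect = lambda,
    true_hr_combined_high = true_hr_combined_high,
    combined_members = combined_members,
    censoring_rate = censoring_rate, baseline_hazard = baseline_hazard,
    progression_hazard = progression_hazard,
    cyt_mean = cyt_mean, cyt_sd = cyt_sd, pdl2_mean = pdl2_mean,
    pdl2_sd = pdl2_sd, tdiv_mean = tdiv_mean, tdiv_sd = tdiv_sd,
    pdl2_loading = pdl2_loading, neoload_log_mean = neoload_log_mean,
    neoload_log_slope = neoload_log_slope,
    neoload_dispersion = neoload_dispersion,
    msi_outlier_fraction = msi_outlier_fraction,
    msi_neoload_mult = msi_neoload_mult, msi_z_shift = msi_z_shift,
    recist_effect = recist_effect, benefit_base_rate = benefit_base_rate
  ), class = "icb_synthetic_config")
}

# exponential censoring rate hitting the target marginal censoring
# fraction: P(censored | hazard h) = c / (h + c), averaged over patients
solve_censoring_rate <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(cc) mean(cc / (hazards + cc)) - target
  uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
}

#' Generate a complete synthetic cohort
#'
#' Draws, per patient, a latent immunogenicity factor `z ~ N(0, 1)`; CYT,
#' PD-L2 and Tdiv as positive-valued linear transforms of correlated
#' latent normals sharing the loading on `z`; a negative-binomial
#' neoepitope load with log-mean increasing in `z`; optional MSI outliers
#' with extreme load but immune signatures drawn at a down-shifted latent
#' value; RECIST with benefit probability increasing in `z`; and
#' exponential survival (death and progression) whose hazards are
#' multiplied by the true HR for patients "high" in the designated
#' biomarker combination (median split on the generated cohort), with
#' independent exponential censoring calibrated to the target censoring
#' fraction.
#'
#' @param config an [synthetic_config()].
#' @return a list of class `icb_synthetic_cohort` with elements
#'   `clinical` (demographics + RECIST + survival columns), `panel`
#'   (patient_id and the four biomarker values), `survival` (patient_id,
#'   pfs_time, pfs_event, os_time, os_event), `truth` (latent z, the
#'   designated spec, per-patient true group, true HR, thresholds, MSI
#'   ids) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "icb_synthetic_config"))
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  lam <- config$latent_effect
  resid <- sqrt(1 - lam^2)

  bio <- withr::with_seed(derive_seed(config$seed, "biomarkers"), {
    z <- rnorm(n)
    n_msi <- round(config$msi_outlier_fraction * n)
    msi <- if (n_msi > 0) sample.int(n, n_msi) else integer(0)
    z_sig <- z
    z_sig[msi] <- config$msi_z_shift  # MSI: cold tumor microenvironment
    u_cyt <- lam * z_sig + resid * rnorm(n)
    u_tdiv <- lam * z_sig + resid * rnorm(n)
    u_pdl2 <- config$pdl2_loading * z_sig +
      sqrt(1 - config$pdl2_loading^2) * rnorm(n)
    mu <- exp(config$neoload_log_mean + config$neoload_log_slope * z)
    mu[msi] <- exp(config$neoload_log_mean +
                     config$neoload_log_slope * 2) * config$msi_neoload_mult
    neoload <- rnbinom(n, size = config$neoload_dispersion, mu = mu)
    list(z = z, z_sig = z_sig, msi = msi,
         cyt = pmax(config$cyt_mean + config$cyt_sd * u_cyt, 0.05),
         pdl2 = pmax(config$pdl2_mean + config$pdl2_sd * u_pdl2, 0.05),
         tdiv = pmax(config$tdiv_mean + config$tdiv_sd * u_tdiv, 0),
         neoload = neoload)
  })

  clin <- withr::with_seed(derive_seed(config$seed, "clinical"), {
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(10, 19) / 29)
    age <- pmin(pmax(round(rnorm(n, 56, 12)), 25), 85)
    diagnosis <- sample(DIAGNOSIS_POOL, n, replace = TRUE)
    treatment <- sample(REGIMEN_POOL, n, replace = TRUE)
    biopsy <- sample(BIOPSY_POOL, n, replace = TRUE)
    prior <- sample(1:7, n, replace = TRUE,
                    prob = c(0.2, 0.3, 0.2, 0.1, 0.05, 0.1, 0.05))
    p_benefit <- plogis(qlogis(config$benefit_base_rate) +
                          config$recist_effect * bio$z_sig)
    benefit <- rbinom(n, 1, p_benefit) == 1
    benefit[bio$msi] <- FALSE  # MSI hypermutators progress on therapy
    recist <- ifelse(benefit,
                     sample(c("CR", "PR", "SD"), n, replace = TRUE,
                            prob = c(2, 5, 4) / 11),
                     "PD")
    data.frame(patient_id = ids, gender = gender, age = age,
               diagnosis = diagnosis, treatment = treatment,
               recist = recist, biopsy_site = biopsy,
               prior_treatments = prior, stringsAsFactors = FALSE)
  })

  panel <- data.frame(patient_id = ids, neoload = bio$neoload,
                      pdl2 = bio$pdl2, cyt = bio$cyt, tdiv = bio$tdiv,
                      stringsAsFactors = FALSE)
  spec <- combination_spec("all_of", members = config$combined_members)
  ga <- assign_groups(panel, spec)
  high <- unname(ga$labels[ids] == "high")

  surv <- withr::with_seed(derive_seed(config$seed, "survival"), {
    hr <- ifelse(high, config$true_hr_combined_high, 1)
    h_death <- config$baseline_hazard * hr
    h_prog <- config$progression_hazard * hr
    death <- rexp(n, rate = h_death)
    prog <- rexp(n, rate = h_prog)
    c_rate <- solve_censoring_rate(h_death, config$censoring_rate)
    cens <- if (c_rate > 0) rexp(n, rate = c_rate) else rep(Inf, n)
    pfs_raw <- pmin(prog, death)
    data.frame(patient_id = ids,
               pfs_time = pmin(pfs_raw, cens),
               pfs_event = as.integer(pfs_raw <= cens),
               os_time = pmin(death, cens),
               os_event = as.integer(death <= cens),
               stringsAsFactors = FALSE)
  })

  clinical <- cbind(clin, surv[, c("pfs_time", "pfs_event",
                                   "os_time", "os_event")])
  structure(list(
    clinical = clinical, panel = panel, survival = surv,
    truth = list(z = setNames(bio$z, ids),
                 z_signature = setNames(bio$z_sig, ids),
                 msi_ids = ids[bio$msi],
                 spec = spec,
                 high = setNames(high, ids),
                 thresholds = ga$thresholds,
                 true_hr = config$true_hr_combined_high),
    config = config
  ), class = "icb_synthetic_cohort")
}

# solve clone counts (K-component mixture: one clone at probability p,
# K-1 equal clones sharing 1-p) whose Shannon entropy equals the target
entropy_clone_counts <- function(target_h, total = 1e4) {
  if (target_h < 0) {
    stop_icb("entropy target must be non-negative", "icbcombo_validation_error")
  }
  if (target_h < 1e-12) return(total)
  k <- ceiling(exp(target_h))
  if (k < 2) k <- 2L
  while (log(k) < target_h) k <- k + 1L  # guard against rounding
  if (abs(log(k) - target_h) < 1e-13) return(rep(total / k, k))
  h_of <- function(p) -p * log(p) - (1 - p) * log((1 - p) / (k - 1))
  root <- uniroot(function(p) h_of(p) - target_h,
                  lower = 1 / k, upper = 1 - 1e-12,
                  tol = .Machine$double.eps^0.9)$root
  c(root, rep((1 - root) / (k - 1), k - 1)) * total
}

random_protein <- function(n_aa) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n_aa, replace = TRUE), collapse = "")
}

# reverse-translate an amino-acid string with fixed codons (deterministic)
AA_TO_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
protein_to_cds <- function(protein) {
  paste0(paste(AA_TO_CODON[strsplit(protein, "")[[1]]], collapse = ""),
         "TAA")
}

SYNTH_ALLELES <- c("HLA-A*02:01", "HLA-B*07:02")
SYNTH_PROT_LEN <- 31L   # protein length of synthetic transcripts
SYNTH_MUT_POS <- 16L    # central residue carrying the missense change

#' Emit molecular input files reproducing target biomarker values
#'
#' Constructive inverse of the biomarker pipeline: writes, per patient, a
#' somatic-variant VCF (one missense variant per synthetic transcript), a
#' shared CDS FASTA, a gene-level expression TSV, per-patient
#' eluted-ligand percentile-rank TSVs, and per-patient CDR3 clone tables,
#' such that running the package's own readers and biomarker functions on
#' these files reproduces each patient's target neoepitope load exactly
#' and the target diversity to within 1e-9 (clone counts from a
#' numerically solved mixture). GZMA and PRF1 rows are set equal to the
#' CYT target (geometric-mean identity) and PDCD1LG2 to the PD-L2 target.
#' Also writes the clinical and survival tables of the cohort.
#'
#' All emitted files are plain text in standard formats (VCF 4.2, FASTA,
#' TSV).
#'
#' @param cohort an [generate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a manifest list of written paths plus the per
#'   patient allele list.
#' @export
generate_molecular_tables <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "icb_synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- cohort$panel
  n <- nrow(panel)
  filt <- neoepitope_filter()
  n_alleles <- length(SYNTH_ALLELES)

  tx_records <- list()   # transcript_id -> cds
  vcf_paths <- character(n)
  rank_paths <- character(n)
  clone_paths <- character(n)
  extra_genes <- character(0)

  molecular_seed <- derive_seed(cohort$config$seed, "molecular")
  withr::with_seed(molecular_seed, {
    for (i in seq_len(n)) {
      pid <- panel$patient_id[i]
      target <- panel$neoload[i]
      # peptide-HLA pairs contributed by one interior missense variant
      n_pep <- sum(vapply(filt$lengths, function(L) {
        min(L, SYNTH_MUT_POS, SYNTH_PROT_LEN - SYNTH_MUT_POS + 1L,
            SYNTH_PROT_LEN - L + 1L)
      }, numeric(1)))
      pairs_per_var <- n_pep * n_alleles
      n_var <- if (target > 0) ceiling(target / pairs_per_var) else 0L

      vcf_rows <- list()
      rank_rows <- list()
      remaining <- target
      for (v in seq_len(n_var)) {
        gene <- sprintf("SYN%s_%02d", pid, v)
        txid <- paste0("tx_", gene)
        # protein with alanine at the mutated residue -> valine via C>T
        prot <- random_protein(SYNTH_PROT_LEN)
        substr(prot, SYNTH_MUT_POS, SYNTH_MUT_POS) <- "A"
        cds <- protein_to_cds(prot)
        tx_records[[txid]] <- list(gene = gene, cds = cds)
        cds_pos <- (SYNTH_MUT_POS - 1L) * 3L + 2L  # GCT -> GTT (A -> V)
        var <- somatic_variant(txid, cds_pos, "C", "T", gene = gene)
        peps <- extract_mutant_peptides(var,
          transcript_model(txid, gene, cds), lengths = filt$lengths)
        grid <- expand.grid(peptide = peps$peptide, allele = SYNTH_ALLELES,
                            stringsAsFactors = FALSE)
        take <- min(remaining, nrow(grid))
        grid$rank <- c(rep(0.5, take), rep(50, nrow(grid) - take))
        remaining <- remaining - take
        rank_rows[[v]] <- grid
        vcf_rows[[v]] <- data.frame(
          CHROM = txid, POS = cds_pos, ID = var$id, REF = "C", ALT = "T",
          QUAL = ".", FILTER = "PASS",
          INFO = sprintf("TRANSCRIPT=%s;CDSPOS=%d;GENE=%s", txid,
                         cds_pos, gene),
          stringsAsFactors = FALSE)
        extra_genes <- c(extra_genes, gene)
      }

      vcf_paths[i] <- file.path(out_dir, sprintf("variants_%s.vcf", pid))
      write_minimal_vcf(do.call(rbind, vcf_rows), vcf_paths[i])
      rank_paths[i] <- file.path(out_dir, sprintf("ranks_%s.tsv", pid))
      rk <- if (length(rank_rows)) do.call(rbind, rank_rows) else
        data.frame(peptide = character(), allele = character(),
                   rank = numeric())
      write.table(rk, rank_paths[i], sep = "\t", quote = FALSE,
                  row.names = FALSE)

      counts <- entropy_clone_counts(panel$tdiv[i])
      cdr3 <- sprintf("CASS%s%04dF", pid, seq_along(counts))
      clone_paths[i] <- file.path(out_dir, sprintf("clones_%s.tsv", pid))
      write.table(data.frame(cloneCount = counts, aaSeqCDR3 = cdr3),
                  clone_paths[i], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  })

  # shared CDS FASTA (header: >transcript_id gene=GENE)
  fasta_path <- file.path(out_dir, "transcripts.fasta")
  lines <- unlist(lapply(names(tx_records), function(txid) {
    c(sprintf(">%s gene=%s", txid, tx_records[[txid]]$gene),
      tx_records[[txid]]$cds)
  }))
  writeLines(lines %||% character(0), fasta_path)

  # gene-level expression: signature genes hit the CYT / PDL2 targets,
  # variant genes get 10 TPM (passing the >0.1 TPM filter)
  genes <- c("GZMA", "PRF1", "PDCD1LG2", unique(extra_genes))
  expr <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, panel$patient_id))
  expr["GZMA", ] <- panel$cyt
  expr["PRF1", ] <- panel$cyt
  expr["PDCD1LG2", ] <- panel$pdl2
  if (length(extra_genes)) expr[unique(extra_genes), ] <- 10
  expr_path <- file.path(out_dir, "expression.tsv")
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
              expr_path, sep = "\t", quote = FALSE, row.names = FALSE)

  clin_path <- file.path(out_dir, "clinical.tsv")
  write.table(cohort$clinical, clin_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  surv_path <- file.path(out_dir, "survival.tsv")
  write.table(cohort$survival, surv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  alleles <- setNames(rep(list(SYNTH_ALLELES), n), panel$patient_id)
  manifest <- list(
    clinical = clin_path, survival = surv_path, expression = expr_path,
    cds_fasta = fasta_path,
    vcf = setNames(vcf_paths, panel$patient_id),
    ranks = setNames(rank_paths, panel$patient_id),
    clones = setNames(clone_paths, panel$patient_id),
    alleles = alleles
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(manifest[c("clinical", "survival", "expression", "cds_fasta")],
      list(vcf = as.list(manifest$vcf), ranks = as.list(manifest$ranks),
           clones = as.list(manifest$clones),
           alleles = lapply(alleles, identity))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  manifest$manifest <- manifest_path
  invisible(manifest)
}

write_minimal_vcf <- function(rows, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=icbcombo-synthetic",
    paste0("##INFO=<ID=TRANSCRIPT,Number=1,Type=String,",
           "Description=\"Transcript id\">"),
    paste0("##INFO=<ID=CDSPOS,Number=1,Type=Integer,",
           "Description=\"1-based position within the CDS\">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (is.null(rows) || nrow(rows) == 0L) character(0) else
    apply(rows, 1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
}
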