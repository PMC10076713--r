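# End-to-end orchestration: derive the biomarker panel from molecular
# inputs, combine, evaluate against survival, and write a report bundle
# with a run manifest.

#' Run the full biomarker pipeline
#'
#' Orchestrates an end-to-end run: read and validate all inputs, derive
#' the four-biomarker panel (neoepitope load from variants + transcripts +
#' ranks + expression; CYT, PD-L2 and T-cell diversity from expression and
#' clone tables), dichotomize and enumerate all combinations, evaluate
#' each against the requested survival endpoints, and write a report
#' bundle: `panel.tsv`, `groups.tsv`, `ranked_combinations.tsv`,
#' `cohort_summary.json` and `run_manifest.json` (recording thresholds and
#' the medians used). The run is deterministic given its inputs. On any
#' stage failure a `FAILED` marker file is written next to the partial
#' outputs and the error is re-raised.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{input_dir}{directory holding a `manifest.json` as written by
#'       [generate_molecular_tables()] (clinical, survival, expression,
#'       CDS FASTA, per-patient VCF/rank/clone paths, alleles).}
#'     \item{out_dir}{output directory.}
#'     \item{tpm_min, rank_max, lengths}{neoepitope filter settings
#'       (defaults 0.1, 2, 8--11).}
#'     \item{load_unit}{`"pairs"` or `"peptides"`.}
#'     \item{entropy_base, pseudocount}{signature settings.}
#'     \item{endpoints}{subset of `c("pfs", "os")`.}
#'     \item{ties}{Cox tie handling.}
#'     \item{time_unit}{unit of the survival columns.}
#'   }
#' @return invisibly, a list with the panel, the ranked table, the cohort
#'   summary and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    stop_icb("config must provide input_dir and out_dir",
             "icbcombo_validation_error")
  }
  manifest_path <- file.path(config$input_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_icb(sprintf("no manifest.json found in %s", config$input_dir),
             "icbcombo_io_error")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  required_inputs <- c("clinical", "survival", "expression", "cds_fasta")
  for (key in required_inputs) {
    if (is.null(man[[key]]) || !file.exists(man[[key]])) {
      stop_icb(sprintf("input '%s' missing or file not found", key),
               "icbcombo_validation_error")
    }
  }
  endpoints <- unlist(config$endpoints %||% c("pfs", "os"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  run <- function() {
    filt <- neoepitope_filter(
      tpm_min = config$tpm_min %||% 0.1,
      rank_max = config$rank_max %||% 2,
      lengths = unlist(config$lengths %||% c(8L, 9L, 10L, 11L)))
    unit <- config$load_unit %||% "pairs"
    entropy_base <- config$entropy_base %||% exp(1)
    pseudocount <- config$pseudocount %||% 0.01

    cohort <- read_clinical_table(man$clinical,
                                  time_unit = config$time_unit %||% "months")
    ids <- cohort$records$patient_id
    expr <- read_expression_matrix(man$expression)
    transcripts <- read_cds_fasta(man$cds_fasta)
    surv_df <- read.delim(man$survival, stringsAsFactors = FALSE)
    surv_df$patient_id <- as.character(surv_df$patient_id)

    clones <- lapply(man$clones, function(p) read_clone_table(p))
    names(clones) <- names(man$clones)

    neoload <- vapply(ids, function(pid) {
      vcf_path <- man$vcf[[pid]]
      if (is.null(vcf_path)) return(NA_integer_)
      variants <- read_variants_vcf(vcf_path)
      provider <- rank_provider_file(man$ranks[[pid]])
      alleles <- unlist(man$alleles[[pid]])
      compute_neoload(variants, transcripts, alleles, provider,
                      expression = expr[, pid], filter = filt, unit = unit)
    }, numeric(1))

    sig <- signature_panel(expr[, ids, drop = FALSE], clones,
                           entropy_base = entropy_base,
                           pseudocount = pseudocount)
    panel <- data.frame(patient_id = ids, neoload = unname(neoload),
                        pdl2 = sig$pdl2[match(ids, sig$patient_id)],
                        cyt = sig$cyt[match(ids, sig$patient_id)],
                        tdiv = sig$tdiv[match(ids, sig$patient_id)],
                        stringsAsFactors = FALSE)
    panel_path <- file.path(out_dir, "panel.tsv")
    write.table(panel, panel_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    specs <- enumerate_combinations()
    groups <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    medians <- list()
    for (spec in specs) {
      ga <- assign_groups(panel, spec)
      groups[[spec$label]] <- unname(ga$labels[ids])
      medians[[spec$label]] <- as.list(ga$thresholds)
    }
    groups_path <- file.path(out_dir, "groups.tsv")
    write.table(groups, groups_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    ranked <- rank_combinations(panel, specs, surv_df,
                                endpoints = endpoints,
                                ties = config$ties %||% "efron")
    ranked_path <- file.path(out_dir, "ranked_combinations.tsv")
    write.table(ranked, ranked_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    summary_path <- file.path(out_dir, "cohort_summary.json")
    cs <- summarize_cohort(cohort)
    jsonlite::write_json(unclass(cs), summary_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    manifest_out <- list(
      package_version = as.character(utils::packageVersion("icbcombo")),
      inputs = man[required_inputs],
      filter = list(tpm_min = filt$tpm_min, rank_max = filt$rank_max,
                    lengths = filt$lengths, load_unit = unit),
      entropy_base = entropy_base, pseudocount = pseudocount,
      median_rule = "high iff value >= median",
      medians = medians, endpoints = as.list(endpoints),
      ties = config$ties %||% "efron")
    manifest_out_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest_out, manifest_out_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(panel = panel, groups = groups, ranked = ranked,
                   summary = cs,
                   paths = list(panel = panel_path, groups = groups_path,
                                ranked = ranked_path,
                                summary = summary_path,
                                manifest = manifest_out_path)))
  }

  tryCatch(run(), error = function(e) {
    writeLines(c("pipeline run failed", conditionMessage(e)), failed_marker)
    stop(e)
  })
}
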