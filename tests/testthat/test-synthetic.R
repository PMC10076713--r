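test_that("the generator is deterministic given a seed and configurable", {
  b1 <- generate_cohort(synthetic_config(n_patients = 20, seed = 101))
  b2 <- generate_cohort(synthetic_config(n_patients = 20, seed = 101))
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$panel, b2$panel)
  expect_identical(b1$survival, b2$survival)
  b3 <- generate_cohort(synthetic_config(n_patients = 20, seed = 102))
  expect_false(identical(b1$panel, b3$panel))

  expect_error(synthetic_config(target_corr_cyt_tdiv = 0.995),
               class = "icbcombo_validation_error")
  expect_error(synthetic_config(n_patients = 3),
               class = "icbcombo_validation_error")
  expect_error(synthetic_config(censoring_rate = 1),
               class = "icbcombo_validation_error")
})

test_that("generated tables satisfy the pipeline's structural contracts", {
  b <- generate_cohort(synthetic_config(n_patients = 29, seed = 5))
  expect_equal(nrow(b$clinical), 29L)
  expect_true(all(b$clinical$recist %in% c("CR", "PR", "SD", "PD")))
  expect_true(all(b$survival$pfs_time <= b$survival$os_time + 1e-12))
  expect_true(all(b$survival$pfs_time > 0))
  expect_true(all(b$panel$neoload >= 0))
  expect_true(all(b$panel$cyt > 0))
  expect_true(all(b$panel$tdiv >= 0))
  # clinical table round-trips through the package's own reader
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(b$clinical, p, sep = "\t", quote = FALSE, row.names = FALSE)
  co <- read_clinical_table(p)
  expect_equal(nrow(co$records), 29L)
})

test_that("MSI outliers carry extreme mutation load but cold immune signatures", {
  b <- generate_cohort(synthetic_config(n_patients = 29, seed = 23))
  msi <- b$panel$patient_id %in% b$truth$msi_ids
  expect_equal(sum(msi), 2L)  # 2/29 default fraction
  expect_gt(min(b$panel$neoload[msi]), max(b$panel$neoload[!msi]))
  expect_lt(mean(b$panel$cyt[msi]), mean(b$panel$cyt[!msi]))
  expect_true(all(b$clinical$recist[msi] == "PD"))
})

test_that("with no latent effect the biomarkers decorrelate", {
  cfg <- synthetic_config(n_patients = 500, seed = 44, latent_effect = 0,
                          msi_outlier_fraction = 0)
  b <- generate_cohort(cfg)
  expect_lt(abs(cor(b$panel$cyt, b$panel$tdiv)), 0.2)
})

test_that("molecular tables invert the pipeline: exact load, 1e-9 diversity", {
  b <- generate_cohort(synthetic_config(n_patients = 6, seed = 9))
  out <- withr::local_tempdir()
  man <- generate_molecular_tables(b, out)
  tx <- read_cds_fasta(man$cds_fasta)
  expr <- read_expression_matrix(man$expression)
  for (pid in b$panel$patient_id) {
    variants <- read_variants_vcf(man$vcf[[pid]])
    load <- compute_neoload(variants, tx, man$alleles[[pid]],
                            rank_provider_file(man$ranks[[pid]]),
                            expression = expr[, pid])
    expect_equal(load, b$panel$neoload[b$panel$patient_id == pid])
    h <- shannon_entropy(read_clone_table(man$clones[[pid]]))
    expect_equal(h, b$panel$tdiv[b$panel$patient_id == pid],
                 tolerance = 1e-9)
  }
  # expression encodes the CYT and PD-L2 targets exactly
  expect_equal(unname(cyt(expr)), b$panel$cyt)
  expect_equal(unname(gene_expression(expr, "PDCD1LG2")), b$panel$pdl2)
})

test_that("a zero-diversity target yields a single clone and a zero load yields no variants", {
  b <- generate_cohort(synthetic_config(n_patients = 6, seed = 9))
  b$panel$tdiv[1] <- 0
  b$panel$neoload[2] <- 0L
  out <- withr::local_tempdir()
  man <- generate_molecular_tables(b, out)
  p1 <- b$panel$patient_id[1]; p2 <- b$panel$patient_id[2]
  expect_equal(nrow(read_clone_table(man$clones[[p1]])), 1L)
  expect_equal(shannon_entropy(read_clone_table(man$clones[[p1]])), 0)
  expect_length(read_variants_vcf(man$vcf[[p2]]), 0L)
})

test_that("entropy inversion hits arbitrary targets to 1e-9 and rejects negatives", {
  for (h in c(0, 0.3, 1.0397, 2.5, log(4), 5.2)) {
    counts <- icbcombo:::entropy_clone_counts(h)
    expect_equal(shannon_entropy(counts), h, tolerance = 1e-9)
  }
  expect_error(icbcombo:::entropy_clone_counts(-1),
               class = "icbcombo_validation_error")
})

test_that("survival generation respects the designated-combination hazard structure", {
  b <- generate_cohort(synthetic_config(n_patients = 300, seed = 61))
  expect_equal(b$truth$spec$label, "NeoLoad+PDL2+CYT")
  # the truth group equals the pipeline's own median-split assignment
  ga <- assign_groups(b$panel, b$truth$spec)
  expect_equal(unname(ga$labels[b$panel$patient_id] == "high"),
               unname(b$truth$high))
  # censoring lands near its target (binomial noise ~0.03 sd at n=300)
  expect_lt(abs(mean(1 - b$survival$os_event) - 0.35), 0.09)
})
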