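test_that("consequence classification follows the genetic code", {
  tx <- transcript_model("t1", "G1", "ATGGCTCGTTTTAAATAA")  # M A R F K *
  # GCT -> GTT : Ala -> Val, missense
  expect_equal(classify_consequence(
    somatic_variant("t1", 5, "C", "T"), tx), "missense")
  # GCT -> GCC : Ala -> Ala, synonymous
  expect_equal(classify_consequence(
    somatic_variant("t1", 6, "T", "C"), tx), "synonymous")
  # 2-bp deletion: frameshift
  expect_equal(classify_consequence(
    somatic_variant("t1", 4, "GCT", "G"), tx), "frameshift")
  # 3-bp in-frame deletion / insertion
  expect_equal(classify_consequence(
    somatic_variant("t1", 3, "GGCT", "G"), tx), "inframe_deletion")
  expect_equal(classify_consequence(
    somatic_variant("t1", 3, "G", "GAAA"), tx), "inframe_insertion")
  # outside the CDS
  expect_equal(classify_consequence(
    somatic_variant("t1", 100, "A", "T"), tx), "other")
  # stop-gain is outside the four extraction classes
  expect_equal(classify_consequence(
    somatic_variant("t1", 13, "A", "T"), tx), "other")  # AAA -> TAA
})

test_that("missense window counts match the closed-form oracle", {
  fx <- make_missense_fixture(30, 15, seed = 1)
  p9 <- extract_mutant_peptides(fx$var, fx$tx, lengths = 9)
  expect_equal(nrow(p9), 9L)
  pall <- extract_mutant_peptides(fx$var, fx$tx, lengths = 8:11)
  expect_equal(nrow(pall), 8L + 9L + 10L + 11L)

  fx1 <- make_missense_fixture(25, 1, seed = 2)
  expect_equal(nrow(extract_mutant_peptides(fx1$var, fx1$tx, lengths = 9)),
               1L)
})

test_that("every emitted peptide has a requested length and differs from its reference window", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(12:40, 1); p <- sample(seq_len(n), 1)
    fx <- make_missense_fixture(n, p)
    peps <- extract_mutant_peptides(fx$var, fx$tx, lengths = 8:11)
    expect_true(all(peps$length %in% 8:11))
    expect_true(all(nchar(peps$peptide) == peps$length))
    ok <- is.na(peps$normal_peptide) | peps$normal_peptide != peps$peptide
    expect_true(all(ok))
  }
})

test_that("extraction equals the brute-force substring oracle on random proteins", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(12:45, 1); p <- sample(seq_len(n), 1)
    L <- sample(8:11, 1)
    fx <- make_missense_fixture(n, p)
    got <- extract_mutant_peptides(fx$var, fx$tx, lengths = L)$peptide
    want <- oracle_peptides(fx$mut_prot, altered = p, L = L)
    expect_setequal(got, want)
  }
})

test_that("frameshift translation emits only novel-register windows", {
  # M A A A A A A A A A A A *  with a 1-bp deletion in codon 4
  prot <- paste0("M", strrep("A", 11))
  tx <- transcript_model("tf", "GF", oracle_cds(prot))
  var <- somatic_variant("tf", 11, "CA", "C")  # frameshift at codon 4
  expect_equal(classify_consequence(var, tx), "frameshift")
  peps <- extract_mutant_peptides(var, tx, lengths = 8)
  expect_true(nrow(peps) >= 1)
  expect_true(all(is.na(peps$normal_peptide)))
  # a frameshift straight into a stop yields nothing
  tx2 <- transcript_model("tf2", "GF2", "ATGGCTAAATAA")
  var2 <- somatic_variant("tf2", 9, "AT", "A")
  expect_equal(nrow(extract_mutant_peptides(var2, tx2, lengths = 8)), 0L)
})

test_that("TMB counts total entries and the non-synonymous subset", {
  expect_equal(tmb_total(data.frame()), 0L)
  cons <- c("synonymous", "synonymous", "synonymous", "missense", "missense")
  expect_equal(tmb_total(data.frame(consequence = cons)), 5L)
  expect_equal(tmb_nonsynonymous(cons), 2L)
  expect_equal(tmb_nonsynonymous(c("frameshift", "inframe_deletion")), 2L)
  expect_equal(tmb_nonsynonymous(character(0)), 0L)
  # subset property over random consequence draws
  set.seed(5)
  for (i in 1:10) {
    cc <- sample(c("missense", "synonymous", "frameshift", "other"),
                 20, replace = TRUE)
    expect_lte(tmb_nonsynonymous(cc), tmb_total(data.frame(consequence = cc)))
  }
})

test_that("neoepitope load applies strict TPM and rank thresholds", {
  tab <- data.frame(
    peptide = sprintf("PEPTIDE%02d", 1:5), allele = "HLA-A*02:01",
    rank = 0.5, expression_tpm = c(0.05, 0.1, 0.2, 3, 50))
  expect_equal(neoepitope_load(tab), 3L)  # > 0.1 excludes 0.05 and 0.1

  tab2 <- data.frame(peptide = "AAAAAAAAA",
                     allele = c("HLA-A*02:01", "HLA-B*07:02"),
                     rank = c(1.9, 2.0), expression_tpm = 10)
  expect_equal(neoepitope_load(tab2), 1L)  # 2.0 fails strict < 2

  expect_equal(neoepitope_load(data.frame(peptide = character(),
                                          allele = character(),
                                          rank = numeric(),
                                          expression_tpm = numeric())), 0L)
  # missing ranks are excluded with a warning
  tab3 <- tab; tab3$rank[2] <- NA
  expect_warning(neoepitope_load(tab3), "excluded")
})

test_that("identical peptides count per mutation but once within a mutation", {
  tab <- data.frame(
    peptide = rep("SAMEPEPTI", 3), allele = "HLA-A*02:01",
    rank = 0.5, expression_tpm = 10,
    mutation_id = c("m1", "m1", "m2"))
  expect_equal(neoepitope_load(tab), 2L)
  expect_equal(neoepitope_load(tab, unit = "peptides"), 2L)
  # per-allele pairs vs distinct peptides
  tab2 <- data.frame(peptide = "SAMEPEPTI",
                     allele = c("HLA-A*02:01", "HLA-B*07:02"),
                     rank = 0.5, expression_tpm = 10, mutation_id = "m1")
  expect_equal(neoepitope_load(tab2, unit = "pairs"), 2L)
  expect_equal(neoepitope_load(tab2, unit = "peptides"), 1L)
})

test_that("rank providers are deterministic and file-backed lookups join correctly", {
  mock <- rank_provider_mock(seed = 4)
  a <- mock(c("AAAA", "CCCC"), c("HLA-A*02:01"))
  b <- mock(c("AAAA", "CCCC"), c("HLA-A*02:01"))
  expect_identical(a, b)
  expect_true(all(a$rank > 0 & a$rank < 100))

  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(peptide = "AAAA", allele = "X", rank = 1.5),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- rank_provider_file(p)
  got <- prov(c("AAAA", "BBBB"), "X")
  expect_equal(got$rank[got$peptide == "AAAA"], 1.5)
  expect_true(is.na(got$rank[got$peptide == "BBBB"]))
})
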