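toy_matrix <- function() {
  m <- matrix(c(4, 9, 5,
                16, 4, 2,
                1, 1, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("GZMA", "PRF1", "PDCD1LG2"),
                              c("pt1", "pt2", "pt3")))
  m
}

test_that("gene lookup returns rows for gene matrices and probe means otherwise", {
  m <- toy_matrix()
  expect_equal(gene_expression(m, "GZMA"), m["GZMA", ])

  probes <- matrix(c(4, 1,
                     6, 2,
                     9, 3), nrow = 3, byrow = TRUE,
                   dimnames = list(c("201_at", "202_at", "203_at"),
                                   c("pt1", "pt2")))
  pm <- data.frame(probe = c("201_at", "202_at", "203_at"),
                   gene = c("PDCD1LG2", "PDCD1LG2", "OTHER"))
  got <- gene_expression(probes, "PD-L2", probe_map = pm)
  expect_equal(unname(got), c((4 + 6) / 2, (1 + 2) / 2))

  pm3 <- data.frame(probe = rownames(probes), gene = "GENEX")
  expect_equal(unname(gene_expression(probes, "GENEX", probe_map = pm3)[1]),
               mean(c(4, 6, 9)))  # three probes {4,6,9}

  expect_error(gene_expression(m, "GZMB"), class = "icbcombo_lookup_error")
})

test_that("PD-L2 spelling variants resolve to one canonical symbol", {
  m <- toy_matrix()
  for (alias in c("PDCD1LG2", "PD-L2", "PDCDLG2", "PDCD1L2")) {
    expect_equal(gene_expression(m, alias), m["PDCD1LG2", ])
  }
})

test_that("CYT is the geometric mean of GZMA and PRF1 with a zero-value pseudocount", {
  m <- toy_matrix()
  expect_equal(unname(cyt(m)), c(sqrt(4 * 16), sqrt(9 * 4), sqrt(5 * 2)))
  # identity CYT(x, x) = x
  m2 <- matrix(c(7, 7), 2, 1, dimnames = list(c("GZMA", "PRF1"), "p"))
  expect_equal(unname(cyt(m2)), 7)
  # zero expression is floored at the pseudocount, not the product
  m3 <- matrix(c(0, 100), 2, 1, dimnames = list(c("GZMA", "PRF1"), "p"))
  expect_equal(unname(cyt(m3)), sqrt(0.01 * 100))
  expect_equal(unname(cyt(m3, pseudocount = 1)), sqrt(1 * 100))
})

test_that("CYT is scale-equivariant", {
  m <- toy_matrix()
  m4 <- m; m4[c("GZMA", "PRF1"), ] <- m[c("GZMA", "PRF1"), ] * 3.5
  expect_equal(cyt(m4), 3.5 * cyt(m))
})

test_that("Shannon entropy matches closed forms and merges duplicate clones", {
  expect_equal(shannon_entropy(rep(1, 4)), log(4))
  expect_equal(shannon_entropy(5), 0)
  expect_equal(shannon_entropy(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  # log base only rescales
  expect_equal(shannon_entropy(c(1, 1, 2), base = 2),
               shannon_entropy(c(1, 1, 2)) / log(2))
  # duplicate sequences merged by summing counts
  tab <- data.frame(cdr3 = c("CASSA", "CASSA", "CASSB"), count = c(1, 1, 2))
  expect_equal(shannon_entropy(tab), shannon_entropy(c(2, 2)))
  expect_warning(h0 <- shannon_entropy(numeric(0)), "empty")
  expect_equal(h0, 0)
  expect_error(shannon_entropy(c(1, -1)), class = "icbcombo_validation_error")
})

test_that("entropy is permutation-invariant, bounded by log richness, and grows under clone splitting", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    counts <- runif(k, 0.5, 20)
    h <- shannon_entropy(counts)
    expect_equal(shannon_entropy(sample(counts)), h)
    expect_lte(h, log(k) + 1e-12)
    # split one clone of count >= 2 into two distinct clones
    j <- which.max(counts)
    split <- c(counts[-j], counts[j] / 2, counts[j] / 2)
    expect_gt(shannon_entropy(split), h)
  }
})

test_that("Wilcoxon rank-sum uses the normal approximation and is symmetric", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)  # U for the first group
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(8)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
})

test_that("Wilcoxon approximation tracks the exact permutation oracle on small groups", {
  set.seed(77)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- round(rnorm(n1), 2); b <- round(rnorm(n2, sample(c(0, 1), 1)), 2)
    approx_p <- wilcoxon_rank_sum(a, b)$p_value
    exact_p <- oracle_wilcox_exact_p(a, b)
    expect_lt(abs(approx_p - exact_p), 0.09)
  }
})

test_that("signature panel assembles per-patient values and flags missing clone data", {
  m <- toy_matrix()
  clones <- list(pt1 = data.frame(cdr3 = c("a", "b"), count = c(1, 1)),
                 pt2 = data.frame(cdr3 = "a", count = 5))
  panel <- signature_panel(m, clones)
  expect_equal(panel$patient_id, c("pt1", "pt2", "pt3"))
  expect_equal(panel$tdiv, c(log(2), 0, NA))
  expect_equal(panel$complete, c(TRUE, TRUE, FALSE))
  expect_true(all(is.finite(panel$cyt)))
  expect_error(signature_panel(m, list(ptX = clones$pt1)),
               class = "icbcombo_validation_error")
})
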