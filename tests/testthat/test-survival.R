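test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  # all censored: S stays at 1
  km <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # events at t = 1, 2 in n = 2 with no censoring: S = 0.5 then 0
  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km2$surv, c(0.5, 0))
  # single subject with an event at 5
  km3 <- km_estimate(5, 1)
  expect_equal(km_surv_at(km3, c(4.9, 5, 6)), c(1, 0, 0))
  # censoring convention: subject censored at an event time stays at risk
  km4 <- km_estimate(c(2, 2, 4), c(1, 0, 1))
  expect_equal(km4$surv[km4$time == 2], 1 - 1 / 3)
})

test_that("without censoring the KM curve equals one minus the empirical CDF", {
  set.seed(14)
  for (i in 1:10) {
    t <- rexp(sample(5:40, 1)) + 0.01
    km <- km_estimate(t, rep(1, length(t)))
    grid <- sort(unique(t))
    ecdf_vals <- vapply(grid, function(g) mean(t <= g), numeric(1))
    expect_equal(km_surv_at(km, grid), 1 - ecdf_vals)
  }
})

test_that("log-rank test is symmetric, degenerate without events, and matches the O-E/V oracle", {
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 0, 1, 1, 0, 1)
  g <- rep(c("high", "low"), each = 3)
  r <- logrank_test(t, e, g)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  set.seed(3)
  t2 <- round(rexp(12) + 0.1, 3); e2 <- rbinom(12, 1, 0.8)
  g2 <- rep(c("high", "low"), 6)
  if (sum(e2) == 0) e2[1] <- 1
  r2 <- logrank_test(t2, e2, g2)
  r2_swap <- logrank_test(t2, e2, ifelse(g2 == "high", "low", "high"))
  expect_equal(r2$chi_square, r2_swap$chi_square)

  # hand-computed observed-minus-expected form on a 6-patient fixture
  tf <- c(1, 3, 5, 2, 4, 6); ef <- c(1, 1, 0, 1, 1, 1)
  gf <- rep(c("high", "low"), each = 3)
  expect_equal(logrank_test(tf, ef, gf)$chi_square,
               oracle_logrank_chisq(tf, ef, gf), tolerance = 1e-8)

  expect_warning(r0 <- logrank_test(c(1, 2), c(0, 0), c("high", "low")),
                 "degenerate")
  expect_equal(r0$p_value, 1)
})

test_that("log-rank p-value is invariant to positive time rescaling", {
  set.seed(6)
  t <- rexp(20) + 0.05; e <- rbinom(20, 1, 0.7); g <- rep(c("high", "low"), 10)
  p1 <- logrank_test(t, e, g)$p_value
  p2 <- logrank_test(t * 365.25, e, g)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Cox HR inverts under label swap and matches the partial-likelihood oracle", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(c(4, 6, 8), 1)
    t <- sample(seq(1, 100), n)  # distinct times: no ties
    e <- rep(1, n); e[sample(n, 1)] <- sample(0:1, 1)
    g <- rep(c("high", "low"), length.out = n)
    cx <- cox_hr(t, e, g)
    if (!cx$converged) next
    beta_oracle <- oracle_cox_beta(t, e, as.integer(g == "high"))
    expect_equal(cx$beta, beta_oracle, tolerance = 5e-4)
    cx_swap <- cox_hr(t, e, ifelse(g == "high", "low", "high"))
    expect_equal(cx_swap$hr, 1 / cx$hr, tolerance = 1e-6)
  }
})

test_that("monotone likelihoods are flagged, never reported as spurious numbers", {
  # zero events in the high group
  cx <- cox_hr(c(1, 2, 3, 4), c(0, 0, 1, 1),
               c("high", "high", "low", "low"))
  expect_false(cx$converged)
  expect_match(cx$note, "zero events|monotone")
  expect_equal(cx$ci95, c(0, Inf))
  # no events at all
  cx2 <- cox_hr(c(1, 2), c(0, 0), c("high", "low"))
  expect_false(cx2$converged)
  # one empty group
  cx3 <- cox_hr(c(1, 2), c(1, 1), c("high", "high"))
  expect_false(cx3$converged)
})

test_that("combination ranking covers every spec x endpoint and is order-invariant", {
  b <- generate_cohort(synthetic_config(n_patients = 40, seed = 12))
  ranked <- rank_combinations(b$panel, survival_df = b$survival)
  expect_equal(nrow(ranked), 17L * 2L)
  expect_setequal(unique(ranked$endpoint), c("pfs", "os"))
  expect_equal(anyDuplicated(ranked[, c("spec", "endpoint")]), 0L)

  perm <- sample(nrow(b$panel))
  ranked2 <- rank_combinations(b$panel[perm, ],
                               survival_df = b$survival[sample(nrow(b$survival)), ])
  expect_equal(ranked2, ranked)

  # HR ascending within endpoint (estimable rows)
  for (ep in c("pfs", "os")) {
    hrs <- ranked$hr[ranked$endpoint == ep & ranked$estimable]
    expect_true(!is.unsorted(hrs))
  }
})

test_that("a truly prognostic single biomarker outranks combinations that dilute it", {
  # biomarker effect carried by NeoLoad alone; other biomarkers pure noise
  set.seed(31)
  n <- 120
  neoload <- rnbinom(n, size = 2, mu = 50)
  high <- neoload >= median(neoload)
  panel <- data.frame(patient_id = sprintf("p%03d", 1:n),
                      neoload = neoload, pdl2 = rnorm(n, 5),
                      cyt = rlnorm(n), tdiv = runif(n, 0, 5))
  os <- rexp(n, rate = 0.1 * ifelse(high, 0.25, 1))
  surv <- data.frame(patient_id = panel$patient_id,
                     os_time = os, os_event = 1L)
  ranked <- rank_combinations(panel, survival_df = surv, endpoints = "os")
  est <- ranked[ranked$estimable, ]
  solo <- which(est$spec == "NeoLoad")
  diluted <- which(est$spec %in% c("NeoLoad+PDL2", "NeoLoad+CYT",
                                   "NeoLoad+Tdiv"))
  expect_true(est$hr[solo] < max(est$hr[diluted]))
})
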