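---
title: "Combined biomarkers for checkpoint-inhibition response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined biomarkers for checkpoint-inhibition response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbcombo)
```

This vignette documents the statistical model behind `icbcombo`, the
parameters a user may want to change, the numerical conventions the
implementation commits to, and what the synthetic-cohort generator does
and does not emulate.

## The problem and the procedure

Immune checkpoint inhibitors (ICIs) blocking the PD-1/PD-L1/PD-L2 axis
benefit only a subset of patients, and in heterogeneous cohorts — many
tumor types, many regimens — no single tumor characteristic separates
responders reliably. The strategy implemented here combines four
biomarkers, each plausibly tracking one facet of an ICI-responsive tumor:

1. **Neoepitope load (NeoLoad).** Somatic variants are classified by
   coding consequence; missense, in-frame indel and frameshift variants
   yield mutant peptides (all 8–11-mer windows covering altered residues).
   Each peptide–HLA pair is kept when the gene of origin is expressed
   (TPM strictly greater than 0.1) and the predicted eluted-ligand
   percentile rank is strictly below 2. The count of passing pairs is the
   load — a proxy for how "visible" the tumor is to CD8 T cells.
2. **PD-L2 expression (PDL2).** Expression of `PDCD1LG2`; on array data,
   the unweighted mean over probes mapping to the gene. High expression
   marks an immunologically active microenvironment and, under anti-PD-1
   therapy, a ligand directly inside the blocked axis.
3. **Cytolytic activity (CYT).** The geometric mean of `GZMA` and `PRF1`
   expression, a standard transcriptional readout of cytotoxic
   lymphocyte activity.
4. **T-cell diversity (Tdiv).** Shannon entropy of CDR3 clone-count
   frequencies recovered from bulk RNA-seq — zero for a monoclonal
   repertoire, `log K` for `K` equally sized clones.

Each biomarker is dichotomized at the cohort median, with "high" meaning
*at or above* the median. Combination rules are either conjunctions over a
subset of the four markers (15 non-empty subsets) or threshold counts
("high in ≥ k of 4", k ∈ {2, 3}), 17 rules in total. Every rule is
evaluated against PFS and OS by Kaplan–Meier estimation, the log-rank
test, and a two-group Cox proportional-hazards model; rules are ranked by
hazard ratio. Between-group biomarker contrasts (progressive disease vs
CR/PR/SD) use the Wilcoxon rank-sum test with normal approximation,
tie-corrected variance and 0.5 continuity correction, since these
quantities are far from normal.

### Assumptions

- The Cox model assumes proportional hazards between the high and low
  groups; with one binary covariate this is the usual two-sample
  assumption and is exactly satisfied by the generator's exponential
  survival model.
- Median dichotomization assumes the cohort itself defines the reference
  distribution; thresholds are therefore cohort-specific and are recorded
  in every group assignment for provenance.
- The biomarker panel must be complete for a patient to be classifiable;
  incomplete patients are flagged and excluded from the affected rules,
  never imputed.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tpm_min` | 0.1 (strict >) | TPM | expression support for the source gene |
| `rank_max` | 2 (strict <) | EL %Rank percentile | standard "weak binder" cutoff for presented ligands |
| `lengths` | 8–11 | amino acids | canonical MHC class I ligand lengths |
| load unit | peptide–HLA `pairs` | — | a peptide presented on two alleles is two chances at recognition; `peptides` counts each peptide once |
| `pseudocount` | 0.01 | expression units | keeps CYT finite when one gene reads zero |
| `entropy_base` | e (nats) | — | base only rescales H and cannot change any median split |
| Cox `ties` | `"efron"` | — | the survival-package default; `"breslow"` available |

Strictness of the two load thresholds is intentional and literal ("> 0.1",
"< 2"): a peptide at exactly TPM 0.1 or rank 2.0 does not pass. Both load
counting units are supported because field conventions differ; the default
(pairs) is declared in the run manifest so either choice is reproducible.

The PD-L2 lookup accepts the spellings `PDCD1LG2`, `PD-L2`, `PDL2`,
`PDCDLG2` and `PDCD1L2`, which all occur in the literature, resolving them
to the canonical `PDCD1LG2`.

## Numerical conventions and degenerate inputs

- **Median for even n** is the midpoint of the two central order
  statistics; ties with the threshold are labelled high by the
  at-or-above rule. With all values equal, everyone is high.
- **CYT pseudocount** replaces *zero* values only. This preserves the
  identities CYT(x, x) = x and CYT(c·g, c·p) = c·CYT(g, p) exactly for
  positive data, while keeping the geometric mean finite at zero; a
  pseudocount added unconditionally would bias every value upward.
- **Stop-gain/stop-loss SNVs** are classified `other` and yield no
  peptides: truncation products are outside the four consequence classes
  handled here.
- **Frameshift translation** runs from the first divergent residue to the
  first stop codon, or to the CDS end when no stop is reached; a
  frameshift that hits a stop before any novel residue yields no peptides.
- **Identical peptides** from different windows of one mutation count
  once; the same peptide string arising from different mutations counts
  per mutation.
- **Monotone Cox likelihoods** (zero events in one group, empty group,
  no events) are flagged (`converged = FALSE`, CI (0, ∞)) rather than
  reported as spurious finite numbers; ranked tables retain the row with
  its flag.
- **Zero events overall** makes the log-rank test degenerate: chi-square
  0, p = 1, with a warning.
- **Wilcoxon with all values identical** returns p = 1.
- **Empty clone tables** have entropy 0 by definition (with a warning);
  fractional clone counts are accepted because read-assignment software
  reports fractional counts for ambiguously assigned reads.

## What the synthetic generator emulates

`generate_cohort()` draws a latent immunogenicity factor `z ~ N(0, 1)` per
patient and builds:

- CYT, PDL2, Tdiv as positive-valued linear transforms of latent normals
  sharing a loading λ on `z`. Two markers with loading λ have Pearson
  correlation λ², so the default λ = √0.744 targets r(CYT, Tdiv) = 0.744
  analytically, not by tuning.
- NeoLoad as negative binomial with log-mean increasing in `z`
  (dispersion 1.3), capturing the heavy right tail of mutation loads.
- MSI hypermutator outliers (default fraction 2/29): extreme mutation
  load, but immune signatures drawn at a down-shifted latent value
  (default −1.5) and RECIST forced to PD — the "cold" hypermutator
  phenotype in which high antigenicity does not translate into benefit.
- RECIST with benefit probability increasing in `z` (logit slope 1.5
  around a marginal benefit rate of 11/29); benefit splits into CR/PR/SD
  at 2:5:4.
- Survival: death and progression times are exponential, with both
  hazards multiplied by the true HR (default 0.25) for patients high in
  the designated combination (default NeoLoad+PDL2+CYT, assigned by the
  pipeline's own median split on the generated panel). PFS is the first
  of progression and death, which keeps the PFS hazard exactly
  proportional too. Independent exponential censoring is calibrated by
  solving `mean(c / (h + c)) = target` for the censoring rate (default
  target 0.35, matching roughly a third of patients alive at analysis).
  Cohort defaults (n = 29, 12 diagnoses, 10 regimens, 10:19 sex ratio)
  mirror a small basket-trial cohort.

A master seed derives per-stage substream seeds (clinical, biomarkers,
survival, molecular) through an arithmetic hash, so each stage is
independently reproducible.

`generate_molecular_tables()` is a constructive inverse: it writes the
molecular files (per-patient VCF with CDS-level annotations, a shared CDS
FASTA, a gene-level expression TSV, per-patient rank and clone TSVs) such
that running the package's own readers and biomarker functions reproduces
each patient's target values — NeoLoad exactly (passing peptide–HLA pairs
are placed by construction, using interior missense variants on synthetic
transcripts), CYT and PDL2 exactly (GZMA = PRF1 = CYT target), and Tdiv to
within 1e-9 (clone counts from a K-component mixture whose mixing weight
is solved numerically against the entropy target; K = ⌈exp(H)⌉ guarantees
the target is below the `log K` ceiling).

**What it does not emulate:** read-level data, real HLA binding biology
(ranks are placed, or mock-hashed, not predicted), linkage between nearby
variants (no phasing), microarray probe-level noise, non-proportional
hazards, informative censoring, and tumor-type heterogeneity beyond the
latent factor. Passing tests therefore demonstrate the correctness of the
analysis machinery and its calibration under the stated model — not that
these biomarkers will stratify any particular real cohort.

## Design choices that were genuinely open

- **Peptide lengths 8–11** are the canonical class I ligand lengths and
  the default of standard binding predictors; exposed in the filter.
- **Load counting unit**: pairs vs distinct peptides is a real ambiguity
  in the field; both are implemented, pairs is the default, and the
  choice is written to the run manifest.
- **Entropy base**: nats. Any base gives identical dichotomizations, so
  the choice is cosmetic; it is still configurable for reporting.
- **k-of-4 rules count the four single-biomarker median splits** — the
  natural reading of "high in three or more of the biomarkers".
- **Wald CIs on log-HR without a penalized fallback**: at n ≈ 29 a
  separation-prone penalized estimate would look deceptively precise;
  flagging is more honest.
- **In-frame indel windows** are paired with the same-coordinate
  reference window when one exists; windows identical to their reference
  counterpart are dropped (they contain no altered residue in register).

## Problem sizes used by the shipped checks

The test suite and acceptance script use: 200 random protein/position/
length cases for the extraction oracle, 100 random peptide tables for
filter monotonicity, cohorts of n = 500 for correlation calibration, and
500 replicate cohorts of n = 200 for hazard-ratio recovery (mean log-HR
and 95% CI coverage). These sizes give Monte-Carlo noise comfortably
below the stated tolerances (e.g. binomial SE of a 95% coverage estimate
at 500 replicates is ≈ 1 percentage point).

## Known limitations

- Consequence classification covers the four classes above plus
  synonymous; no splice, UTR or stop-codon effects, and no VEP-style
  transcript selection.
- The neoepitope arm consumes externally supplied (or mocked) binding
  ranks; it never runs a predictor.
- Survival machinery is two-group only: no covariate adjustment,
  competing risks, or interval censoring.
- Median splits discard within-group information; patients near the
  median are borderline by construction. Continuous-score modeling and
  learned combinations are deliberately out of scope at this cohort size.
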