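---
title: "Methods: whole-exome molecular subtyping of endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-exome molecular subtyping of endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsubtype)
```

## The classification problem

Endometrial carcinoma falls into four prognostically distinct molecular
subtypes: **POLE** (ultramutated, polymerase-epsilon exonuclease-domain
mutant, excellent prognosis), **MSI** (mismatch-repair deficient,
hypermutated, intermediate prognosis), **CN-low** (copy-number quiet,
endometrioid-like, intermediate prognosis) and **CN-high** (copy-number
driven, serous-like, poor prognosis). The original definition of these
classes required an integrated multi-platform assay (SNV calls, SNP
arrays, methylation, mRNA, RPPA). This package determines all four
subtypes from quantities derivable from **whole-exome sequencing alone**
— somatic small-variant calls, absolute copy-number segments with
ploidy, and an MSI status — so that a single routine assay suffices.

Upstream alignment, variant calling, copy-number segmentation and MSI
scoring are deliberately out of scope: the package consumes their
standard outputs (VCF or MAF-like TSV; SEG-style segment tables; a
clinical/MSI TSV; a BED gene model).

## The hierarchical cascade

Each sample receives exactly one label, assigned with strict precedence:

1. **POLE** — on the pyrimidine-collapsed somatic substitution spectrum,
   a sample is POLE iff

   $$ n_{\mathrm{SNV}} > 500
      \quad\wedge\quad
      \frac{n_{C>A}}{n_{\mathrm{SNV}}} > 0.2
      \quad\wedge\quad
      \frac{n_{C>G}}{n_{\mathrm{SNV}}} < 0.03, $$

   with all three inequalities strict. Every substitution is collapsed
   to the six pyrimidine-reference classes (G>T counts as C>A, and so
   on), so the C>A and C>G fractions are strand-symmetric shares of all
   somatic SNVs. A zero-SNV sample has both rates defined as 0 and can
   never be POLE (it already fails the burden gate).
2. **MSI** — remaining samples are MSI iff MSI-high. Categorical labels
   are normalised on input; a numeric score in $[0,1]$ passes the gate
   at `score >= 0.5` (the tie goes to MSI-high; the cutoff is a
   parameter of `pole_params()`). An *unknown* MSI status for a sample
   that reaches this stage is an error rather than a silent CN call.
3. **CN-high** — remaining samples are CN-high iff the Gaussian naive
   Bayes posterior of copy-number cluster-4 membership is at least 0.5
   (the canonical Bayes decision rule; configurable).
4. **CN-low** — everything else.

Precedence is absolute: a sample that satisfies the POLE rule is POLE
even when it is also MSI-high, mirroring the mutual exclusivity of the
reference classification.

## Copy-number features and the cluster-4 model

The CN-high stage is a binary classifier of membership in the
copy-number cluster 4 of the reference taxonomy (the serous-like,
highly altered cluster), trained on samples with known cluster labels
binarised to cluster 4 vs clusters 1–3.

Segments are called **gain** when the absolute copy number is at least
`gain_margin` (default 0.5) above the sample ploidy and **loss** when at
least `loss_margin` below it. Margins are relative to ploidy rather
than to a fixed diploid baseline: with WES-derived absolute copy
numbers this keeps a genome-doubled tumor from being called
"all gain" and keeps ploidy itself an informative, non-redundant
feature. The feature vector per sample is, in fixed order:

* gain and loss segment counts per sample (2),
* gain and loss segment counts per chromosome over the fixed universe
  1–22, X (46) — no Y, as endometrial carcinoma is a female malignancy,
* gain and loss overlap counts for the top-*k* most frequently altered
  genes, default $k = 25$ (50) — a gene counts one gain per gain
  segment overlapping it by at least one base,
* ploidy and the altered-genome fraction, total altered bases divided
  by $3100\,\mathrm{Mb}$ (2),

giving 100 features at the defaults. "Most frequently altered" means
the largest fraction of training samples in which the gene overlaps at
least one gain or loss segment, with ties broken deterministically by
genomic position; genes never altered in training are not selectable.
Gene selection is data-dependent, so during cross-validation it is
**re-run inside every training fold** and the resulting list is imposed
on the held-out fold — held-out samples never influence the feature
space. For the final model the selection runs once on the full
training set.

The classifier itself is a from-scratch binary Gaussian naive Bayes:
class priors are observed frequencies; each feature gets a per-class
mean and unbiased variance; posteriors are computed in log space and
normalised by log-sum-exp. Count features are deliberately modelled
with the same Gaussian likelihood as the continuous ones — the features
are strongly correlated anyway, the conditional-independence assumption
is already violated by construction, and empirically the model is
robust to both. Variances are floored at $10^{-9}$ times the largest
per-feature pooled variance (absolute $10^{-9}$ if all features are
constant) so constant features contribute a flat likelihood instead of
a degenerate density; the floor is tied to the data scale, which we
prefer to additive count smoothing because half the features are not
counts.

### Cross-validation conventions

`cross_validate()` uses stratified $k$-fold assignment (default
$k = 5$): within each class, members are shuffled under a fixed,
overridable seed and dealt round-robin, so per-class fold sizes differ
by at most one. Reported "averaged" metrics are **unweighted means over
folds**; pooled metrics over the concatenated out-of-fold predictions
are reported alongside, since the two conventions differ slightly and
published figures rarely state which was used. ROC-AUC is the
Mann–Whitney rank statistic with midranks for ties.

## Evaluation protocol

`evaluate_cohort()` reproduces the published comparison protocol
against a reference classification:

* the 4×4 confusion matrix (rows = reference, columns = predicted) with
  half-up whole-percent row percentages,
* per-class precision/recall/F1 (empty predicted column → precision 0;
  both zero → F1 0, the standard conventions) and macro / weighted
  (reference-class-size) averages; over a complete matrix weighted
  recall equals accuracy exactly,
* a Pearson chi-square test of homogeneity on the 2×4 table of the two
  class distributions (df = 3, no continuity correction),
* Kaplan–Meier curves per subtype under both labelings via
  `survival::survfit`, landmark survival at 36 months using the step
  value at the largest event time ≤ t, and the 4-group log-rank test
  via `survival::survdiff` (df = 3). "Multigroup" rather than
  covariate-adjusted: one omnibus p-value across the four curves.
  Records lacking follow-up are dropped from the survival analysis
  only.

The KM/log-rank/chi-square machinery is delegated to `survival` and
`stats`; the test suite additionally cross-checks these against
hand-computed product-limit values and a brute-force
observed-minus-expected log-rank oracle at $10^{-10}$ tolerance, and
the naive Bayes posterior against a direct density-product oracle and
`e1071::naiveBayes`.

## The synthetic cohort generator

There is no public desk-scale input on which the full pipeline could be
demonstrated — the real cohort's alignments are protected-access and
its variant calls come from a proprietary pipeline. The generator
(`simulate_cohort()`) therefore emulates exactly the statistical
structure the cascade relies on, with defaults fixed once:

* **Subtype proportions** 7/28/39/26% (POLE/MSI/CN-low/CN-high) at
  cohort size $n = 232$, the published cohort's composition; labels are
  drawn multinomially.
* **SNV burden** per subtype is log-normal — median 3000 (sd(log) 0.4)
  for POLE, 900 for MSI, 60 and 80 for CN-low/CN-high (sd(log) 0.5),
  matching the ultramutated / hypermutated / quiet ordering of the
  subtypes with a heavy upper tail.
* **Spectra**: POLE draws substitutions with C>A weight 0.30 and C>G
  weight 0.01 (C>T 0.40, remainder spread), so POLE samples satisfy the
  rule with probability > 0.99; all other subtypes use a generic
  C>T-dominated spectrum (C>A 0.08, C>G 0.05) and essentially never
  trip it, even hypermutated MSI. Each event is emitted on a random
  strand so the collapsing step is exercised; ~3% indels are mixed in.
* **MSI-high probability** 1.0 for MSI, 0.30 for POLE (POLE tumors are
  frequently also MSI-high; precedence must resolve them), 0 otherwise.
* **Copy number**: segments tile each chromosome (breakpoints uniform);
  CN-low-like subtypes get ~26–30 segments with 5% altered and ploidy
  ≈ 2.0, CN-high ~60 segments with 50% altered and ploidy ≈ 3.1 — more
  than five-fold the altered-genome fraction of CN-low, the separation
  the cluster-4 model needs. `cn_cluster` is 4 for CN-high samples and
  uniform over 1–3 otherwise.
* **Survival**: exponential event times with 36-month survival targets
  1.00 / 0.81 / 0.87 / 0.60 for POLE / MSI / CN-low / CN-high
  ($h = -\ln S_{36} / 36$ per month; POLE hazard exactly 0), plus an
  independent exponential censoring hazard of 0.012 per month (median
  follow-up ≈ 58 months). Follow-up is the minimum of the two times.

One master seed fans out into independent substream seeds for labels,
variants, copy number, survival and the gene model, so each stage is
reproducible in isolation. The gene model places 300 genes (length
log-normal around 50 kb) uniformly across the genome.

What the generator does **not** emulate: trinucleotide-context
signatures, recurrent focal amplicons or driver genes, correlated
MSI/burden noise, non-exponential hazards, cohort-level batch effects.
Passing tests on synthetic cohorts therefore demonstrate the
correctness and internal consistency of the implementation — rule
boundaries, leakage-free feature selection, metric identities, survival
estimators — not clinical performance on real tumors, which depends on
upstream calling quality the package does not control.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally (VCF and SEG
  native); BED input is converted on read. Chromosome names are
  normalised by stripping a leading `chr`.
* SEG input carries absolute copy number by default; `read_seg(...,
  log2 = TRUE)` converts log2 ratios as $\mathrm{ploidy} \cdot
  2^{\mathrm{value}}$ on read. Missing ploidy column defaults to 2.
* Multi-allelic VCF records are split per ALT allele before SNV
  counting; duplicate calls are collapsed; records failing FILTER are
  dropped.
* All three POLE inequalities are strict, exactly as the rule is
  stated; the boundary cases 500 SNV / 0.2 / 0.03 all fail.
* The cascade computes the CN posterior only for samples that reach the
  CN stage; `full_evidence = TRUE` fills it in for POLE/MSI samples for
  audit purposes without changing any label.
* Problem sizes used by the test-suite simulations (cohorts of 12–400
  samples, 2000 per group for the KM convergence check) were chosen as
  the smallest sizes at which the checked statistical bounds are
  meaningful.

## Known limitations

* MSI status is an input, not a call; a cohort without MSI information
  cannot be classified past the POLE stage.
* The cluster-4 model must be trained on a cohort with known cluster
  labels; no pre-trained model for real data ships with the package
  (the published training data are not redistributable).
* Gaussian likelihoods on count features are a pragmatic approximation;
  a kernel or discretised variant may behave better on sparse gene
  counts.
* With fewer than `top_k_genes` genes ever altered in training, the
  feature vector shrinks accordingly; models and feature matrices are
  only compatible when built from the same selection.
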