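# ecsubtype

Whole-exome molecular subtyping of endometrial cancer.

Endometrial carcinoma splits into four prognostically distinct molecular
subtypes — **POLE** (ultramutated, excellent prognosis), **MSI**
(mismatch-repair deficient, hypermutated), **CN-low** (copy-number
quiet) and **CN-high** (copy-number driven, serous-like, poor
prognosis). The original taxonomy needs an integrated multi-platform
assay; this package determines all four subtypes from quantities a
single whole-exome sequencing workflow already yields: somatic
small-variant calls, absolute copy-number segments with ploidy, and an
MSI status. It is aimed at bioinformaticians evaluating WES-only
subtyping against a multi-platform reference classification.

## The method

Each sample is labelled by a hierarchical cascade with strict
precedence:

1. **POLE** iff, on the pyrimidine-collapsed substitution spectrum,
   n<sub>SNV</sub> > 500 **and** n<sub>C>A</sub>/n<sub>SNV</sub> > 0.2
   **and** n<sub>C>G</sub>/n<sub>SNV</sub> < 0.03 (all strict);
2. otherwise **MSI** iff MSI-high;
3. otherwise **CN-high** iff a Gaussian naive Bayes model puts the
   posterior probability of copy-number cluster-4 membership at ≥ 0.5.
   The model uses 100 segment-derived features: gain/loss counts per
   sample, per chromosome (1–22, X) and per top-25 most frequently
   altered training genes, plus ploidy and the altered-genome fraction;
4. otherwise **CN-low**.

The package also ships the full evaluation protocol (confusion matrix,
macro/weighted metrics, chi-square comparison of class distributions,
Kaplan–Meier / log-rank survival concordance), stratified 5-fold
cross-validation with per-fold gene selection, a synthetic cohort
generator emulating the per-subtype mutation, copy-number, MSI and
survival structure, and an `ecsub` command-line interface
(`simulate`, `load`, `spectrum`, `cnfeat`, `train`, `cv`, `classify`,
`evaluate`). See the methods vignette (`vignettes/methods.Rmd`) for the
model details and design rationale.

## Worked example

Train the cluster-4 model on a synthetic 240-sample cohort with known
cluster labels, then classify and evaluate an independent 232-sample
cohort:

```r
library(ecsubtype)

genes  <- simulate_gene_model(300, seed = 101)
train  <- simulate_cohort(n = 240, seed = 102, genes = genes)
cohort <- simulate_cohort(n = 232, seed = 103, genes = genes)

model <- ec_classifier(train$cn, train$clinical$cn_cluster == 4, genes)
model
#> Endometrial-cancer molecular subtype classifier
#>   POLE rule: >500 SNV, C>A rate > 0.20, C>G rate < 0.03
#>   MSI gate: MSI-high status (score cutoff 0.5 )
#>   CN-high: naive Bayes cluster-4 posterior >= 0.50 (100 features,
#>   25 genes; trained on 240 samples, 64 positive)

cross_validate(train$cn, train$clinical$cn_cluster == 4,
               genes = genes, k = 5, seed = 104)
#> Stratified 5-fold cross-validation (positive class: TRUE)
#> Fold-averaged:
#>  accuracy precision    recall        f1   roc_auc
#>    0.9584    0.8757    1.0000    0.9312    0.9859

calls <- predict(model, cohort$variants, cohort$clinical, cohort$cn)
calls
#> Molecular subtype calls for 232 samples:
#>    POLE     MSI  CN-low CN-high
#>      13      63      87      69

evaluate_cohort(calls, cohort$clinical)
#> Confusion matrix (rows = reference, columns = predicted), n = 232
#>          predicted
#> reference POLE MSI CN-low CN-high
#>   POLE      13   0      0       0
#>   MSI        0  63      0       0
#>   CN-low     0   0     87       4
#>   CN-high    0   0      0      65
#> ...
#> Macro-averaged:   accuracy=0.9828  precision=0.9855  recall=0.989  f1=0.9869
#> Chi-square homogeneity: X2 = 0.2093, df = 3, p = 0.9761
#> 36-month survival (predicted): POLE=1  MSI=0.83  CN-low=0.88  CN-high=0.72
#> Log-rank (predicted): Log-rank test: X2 = 19.7506, df = 3, p = 0.0001912
```

Here the cascade recovers 98.3% of the generating labels; the
chi-square p-value says the predicted and reference subtype
distributions are statistically indistinguishable, and the log-rank
tests confirm that the predicted labels stratify survival (POLE best,
CN-high worst) just as the reference labels do.

The same pipeline from a shell:

```sh
ecsub simulate --out cohort/ --n 232 --seed 7
ecsub train    --seg cohort/segments.seg --genes cohort/genes.bed \
               --clinical cohort/clinical.tsv --out model.json
ecsub classify --variants cohort/variants --seg cohort/segments.seg \
               --clinical cohort/clinical.tsv --model model.json \
               --out calls.tsv
ecsub evaluate --calls calls.tsv --clinical cohort/clinical.tsv --out report/
```

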