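---
title: "Sparse discriminant modeling of RNA-Seq SNV allele fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse discriminant modeling of RNA-Seq SNV allele fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(snvdisc)
```

## The problem

Single nucleotide variants called from RNA-Seq carry more information
than their mere presence: the *allele fraction* (AF) — reads supporting
the variant allele over total reads at the position — is a continuous
quantity that reflects allele-specific expression, clonal expansion or
depletion, and copy-number changes, all folded together. `snvdisc`
treats the per-sample AFs of many SNVs as a feature matrix and asks
which small subset of SNVs best discriminates two phenotype groups
(say, relapse versus disease-free, or two tumour subtypes), producing
both a classifier and a ranked list of candidate marker SNVs.

## The allele-fraction matrix

The container is a features × samples matrix `SNVM` with
`SNVM[i, j]` the AF of SNV *i* in sample *j*. Three cell states are
distinguished:

* an AF in `(0, 1]`: the variant was called and the position had at
  least `coverage_threshold` reads (default **10**);
* `0`: the position was adequately covered but no variant was called —
  an *observed absence*, which participates in all statistics;
* `NA`: read coverage below the threshold — *no information*, masked
  from every computation.

Keeping 0 and `NA` separate matters: a zero is evidence that the
variant allele is not expressed, a masked cell is not evidence of
anything. Coverage comes from a depth column in the call files or from
a separate per-locus, per-sample depth table; with only per-record
depths, a cell without any record has unknown coverage and is `NA`.

Feature identity is the full `(chrom, pos, ref, alt)` tuple, so two
alternate alleles at one position are two features. Positions are
1-based internally; BED input/output uses 0-based half-open intervals.
Sub-models restrict features by ANNOVAR-style region class (with
nonsynonymous exonic SNVs also matching an `exonic` request, since they
are a subset) or to catalogued RNA-editing sites, and a minimum number
of samples with non-zero AF (typically 3 for a ~20-sample cohort, 6 for
a ~80-sample cohort) removes near-private variants.

## The sparse PLS-DA core

The classifier is a two-class sparse partial least squares discriminant
analysis, written from scratch in this package:

* The class labels are dummy-coded into an *n* × 2 indicator matrix
  **Y**, column-centered. Features are centered and scaled to unit
  variance using their observed (non-`NA`) training entries; constant
  features standardize to zero and can never be selected.
* Each component finds a weight vector **w** (unit norm) maximising
  covariance between **Xw** and the centered response, subject to
  exactly *K* nonzero entries. Sparsity uses soft-thresholding at the
  (*K*+1)-th largest absolute weight — survivors are shrunk by the
  threshold and renormalised. Ties straddling the *K*-th position are
  broken toward the lower feature index, and the threshold is lowered
  to the largest absolute weight strictly below the kept minimum so the
  exactly-*K* contract holds even then.
* Missing training entries are tolerated NIPALS-style: inner products
  sum over observed entries and are rescaled by total/observed counts,
  and deflation only touches observed cells. With no missing data these
  reduce exactly to ordinary inner products.
* Prediction standardizes new samples with the *training* parameters
  and fills each remaining `NA` of feature *f* with the mean of the two
  training-group means of the standardized values of *f* — the midpoint
  carries no group information, so imputation cannot leak labels. The
  continuous score is the predicted dummy value of the second group
  minus the first; a positive score calls the second group, with exact
  ties going to the more prevalent training group.

One component is the default: a two-class discriminant needs a single
direction, and the single weight vector is what the feature ranking
uses. More components are supported (`n_components`), with score
deflation between components.

## Choosing K, and knowing whether the model is real

*K* is tuned by nested cross-validation. For every outer fold of every
repeat (default fifteen 10-fold cross-validations, i.e. 150 outer
folds), an inner cross-validation on the outer-training set scores each
candidate *K* by pooled inner-test AUC; the best *K* (ties to the
smallest — parsimony) is recorded. A Gaussian kernel density
(Silverman's rule-of-thumb bandwidth, 512-point grid spanning the data
range ± 3 bandwidths — the defaults of `stats::density`) is estimated
over the recorded values and the optimum is the rounded argmax, clamped
to the tested range. The mode is deliberately robust to the long right
tail that AUC-flat regions of the grid produce.

Performance at the chosen *K* is summarised by repeated
cross-validation: per repeat, test scores are pooled across folds
(avoiding undefined single-class fold AUCs) giving one AUC, accuracy
and per-group sensitivity; the summary averages repeats and attaches a
normal-approximation 95% CI (`mean ± 1.96·sd/√repeats`). AUC is
computed as the Mann–Whitney pair statistic with ties counted ½.

Significance is a label-permutation test: each of `n_perm` (default
1000) permutations shuffles the labels and runs one fresh 10-fold
cross-validation at the same *K*; the p-value is the fraction of
permutations whose AUC reaches the true model's. A zero count is
reported as `<1/n_perm`. Folds are stratified by class throughout —
with small unbalanced cohorts unstratified folds can lose a class from
a training split; a fold draw that would do so is re-drawn.

The inner-CV criterion is AUC (configurable consequences are minor; it
is also the permutation statistic), and all fold draws flow from a
single user seed, making the entire select → evaluate → permute
pipeline bit-reproducible.

## Ranking and univariate comparators

The final model is refit on all samples at the optimal *K*; selected
SNVs are ranked by absolute loading. Each is annotated with two
univariate p-values:

* **Exact 2 × 4 Fisher test.** Per locus, a groups × alleles (A, C, G,
  T) table counts samples with detectable levels of each allele —
  reference detectable when AF < 1, variant when AF > 0, `NA` samples
  skipped. Presence is binary, so the test sees only differential
  *abundance* of alleles. The p-value is computed by full enumeration
  of tables with the observed margins (multivariate hypergeometric,
  two-sided by probability ordering), feasible at cohort-scale counts;
  zero-margin columns are dropped first.
* **Wilcoxon rank-sum** on the AF values themselves — differential
  *magnitude*. `NA` excluded, zeros kept; exact small-sample
  distribution without ties, otherwise the tie-corrected normal
  approximation with continuity correction.

A Friedman rank-sum test (features as blocks, methods as treatments,
tie-corrected) quantifies whether the multivariate ranking disagrees
systematically with the univariate ones, restricted to the selected
features. Note that a pure reversal of one method against two identical
others balances within-block ranks and yields statistic 0; the test
detects *consistent* rank shifts, not arbitrary disagreement. Fully
tied blocks (identical rankings) are reported as statistic 0, p = 1.

Finally, `ase_enrichment()` asks whether the genes hosting selected
SNVs are enriched for significant allele-specific expression: the
fraction of significant, testable gene/sample pairs among selected
genes is compared with 1000 equally-sized random gene subsets; the
p-value is the fraction of subsets at or above the observed fraction
and the fold is observed over null mean. ASE calls themselves (e.g.
from MBASED) are consumed as an input table, not recomputed.

## The synthetic generator

`generate_dataset()` produces matrices with the assumed structure and a
known answer key, so every claim above is testable without patient
data. It emulates:

* a zero-inflated background — each cell is non-zero with probability
  0.2, and non-zero AFs are Beta(2, 2);
* informative features of two kinds, mirroring the two signal modes the
  univariate tests separate: *abundance* shifts (non-zero probability
  0.2 vs 0.6 between groups) and *magnitude* shifts (non-zero
  probability 0.7 in both groups, Beta means 0.35 vs 0.65 at
  concentration 8); the default alternates the two kinds;
* coverage-driven missingness — depths are negative binomial (size 5)
  with the mean solved so that the sub-threshold probability equals the
  requested `na_rate` (default 10% at threshold 10);
* a gene map (~3 SNVs per gene) and an ASE truth table in which genes
  hosting informative SNVs, plus a few background genes, are
  ASE-positive with testable pairs significant at rate 0.5 against a
  0.05 background.

What it does *not* emulate: linkage between nearby SNVs,
sample-specific coverage profiles, sequencing or alignment artifacts,
multi-allelic sites, or batch structure. Passing tests on generated
data therefore demonstrate the statistical machinery — masking
semantics, selection, calibration, ranking — not robustness to the
failure modes of real variant calling, which the upstream pipeline must
handle.

## Numerical and design choices

* **Problem sizes.** The package's own validation uses desk-scale
  designs: recovery runs use 40 samples/group × 500 features with 3 × 10-fold
  outer and 5-fold inner CV over K ∈ {10, …, 60}; calibration uses 100
  null datasets × 200 permutations. These sizes give stable Monte-Carlo
  behaviour (binomial 95% bounds) while keeping a full run in minutes.
* **Degenerate inputs.** Constant features → zero weights, never
  selected; a group with no observed training values for a feature →
  imputation falls back to the other group's mean (logged); `keep_k`
  above the feature count is clamped with a warning; single-class input
  is an error; all-zero Fisher tables and fully-`NA` Wilcoxon groups
  are errors rather than silent 1s.
* **Tie-breaks.** Sparsity ties → lower feature index; inner-CV ties
  between K values → smallest K; prediction score exactly 0 → more
  prevalent training group. All deterministic.
* **Worked example sizes in figures.** Heatmaps cluster standardized
  AFs (average linkage, Euclidean distance) with `NA` replaced by the
  imputation midpoint *for the distance computation only*; displayed
  cells keep their `NA`, drawn black. Boxplots include zeros in the box
  statistics but only plot non-zero points.

## A small worked run

```{r, eval = FALSE}
ds <- generate_dataset(generator_spec(n_per_group = 20, n_features = 300,
                                      n_informative = 10, rng_seed = 42))
sel <- nested_cv_select_k(ds$matrix, k_grid(5, 50, 5),
                          cv_design(n_folds = 10, n_repeats = 3,
                                    rng_seed = 1), inner_folds = 5)
perf <- evaluate_model(ds$matrix, sel$optimal_k,
                       cv_design(n_folds = 10, n_repeats = 5, rng_seed = 2))
perm <- permutation_test(ds$matrix, sel$optimal_k, perf$auc_mean,
                         n_perm = 200, design = cv_design(rng_seed = 3))
rk <- final_rank(ds$matrix, sel$optimal_k)
head(rk)
```

## Known limitations

Two groups only; one response; SNVs only (no indels or multi-allelic
sites); the permutation test's resolution is `1/n_perm`; the normal CI
on the AUC ignores the correlation between repeats on the same data and
is best read as a stability band, not a coverage-calibrated interval;
and the 2 × 4 Fisher enumeration, while exact, grows with the smaller
row margin and is intended for cohort-scale (tens to low hundreds of
samples) tables.
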