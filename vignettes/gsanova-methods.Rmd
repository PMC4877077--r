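---
title: "Gene set analysis of variance: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set analysis of variance: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsanova)
```

## The problem

Small-n treatment time courses (here the motivating design: rat trigeminal
ganglia profiled by bulk RNA-seq in three groups — vehicle, 30 minutes and
90 minutes after infusion of the nitric-oxide donor glyceryl trinitrate,
with 2–4 animals per group) rarely yield many genome-wide-significant genes.
Pathway-level aggregation recovers power, but the classical two-class
enrichment statistics (t-like gene scores) cannot express "changed somewhere
across k groups". This package scores each gene with the one-way ANOVA
f-statistic, which measures change across any number of groups
simultaneously, and carries that score through a self-contained
gene-set-analysis scheme: random-set standardization, group-label
permutation, a pooled global null, and q-values.

## The method

For gene `g` with expression values `x_ij` (group `i`, replicate `j`),
group sizes `n_i`, group means `x̄_i`, grand mean `x̄`, `n` samples and `k`
groups:

$$
f_g = \frac{n-k}{k-1}\;
\frac{\sum_{i=1}^{k} n_i\,(\bar x_i - \bar x)^2}
     {\sum_{i=1}^{k}\sum_{j=1}^{n_i} (x_{ij} - \bar x_i)^2}
$$

the standard one-way ANOVA F: the ratio of between-group to within-group
variation, scaled by its degrees of freedom. Unexpressed genes (by default,
all-zero counts; configurable via a minimum-total-count rule) are assigned
`f = 0`.

A gene set's **raw score** is the mean `f` over its members present in the
expression matrix. The **standardized score** centers and scales the raw
score by the mean and standard deviation of the scores of `n_random_sets`
(default 1000) random gene sets of identical size drawn uniformly without
replacement from the full gene universe — unexpressed genes included, since
they are legitimate draws with `f = 0`. **Nominal p-values** come from
recomputing standardized scores under `n_permutations` (default 1000)
uniform shuffles of the group-label vector (which preserve group sizes);
the add-one upper tail `p = (1 + \#\{z_{null} \ge z_{obs}\})/(B+1)` keeps p
in `(0, 1]`. **Pooled p-values** use the same formula against the
permutation scores pooled across all sets — a common global null — and feed
the **q-value** step-up adjustment; with `pi0_method = "fixed_one"` this is
exactly Benjamini–Hochberg, while `"storey_smoother"` estimates the true
null proportion with the cubic-smoother-on-a-lambda-grid extrapolation.
Sets with `q < q_cutoff` (default 0.25, the customary enrichment screen
threshold) are flagged significant. Significance is one-sided by
construction: `f` is non-negative and large under change in any direction,
so only the upper tail is of interest.

### Worked toy

```{r toy}
em <- expression_matrix(matrix(c(1, 2, 3, 4), nrow = 1,
                               dimnames = list("g1", paste0("s", 1:4))),
                        "identity")
design <- sample_design(paste0("s", 1:4), c("a", "a", "b", "b"))
gene_f_statistics(em, design)$f  # between SS 4, within SS 1, scale 2 -> 8

# exhaustive standardization on a 4-gene universe
standardize_score(2.5, 2, c(0, 1, 2, 3), method = "exhaustive")
```

## Assumptions and what the f-score does and does not test

The f-statistic assumes (approximately) homoscedastic, roughly Gaussian
expression values within groups; this is why counts are first transformed.
The permutation null requires exchangeability of samples across groups
under the null, which a randomized design provides. The mean-f set score is
a *self-contained* statistic of "members changed", not a competitive test
against genes outside the set — although the random-set standardization
injects a competitive element by referencing the set score to same-size
random sets from the same universe.

## Count transform

The expression estimates are `log2(count / size_factor + pseudocount)` with
median-of-ratios size factors and pseudocount 1. A shrinkage-based
regularized-log transform would further stabilize low-count genes, but the
enrichment machinery only requires *some* homoscedastic log-scale estimate;
the simple transform keeps the package dependency-light and the
`transform_tag` on every `expression_matrix` records exactly what was
applied. Low-count genes are noisier under this transform than under a
shrunk one — a known limitation; with 3–4 replicates per group the effect
on set-level means is modest.

## Sample QC

Outlier screening computes Euclidean distances between transformed samples
and an average-linkage dendrogram (exported as Newick text for manual
review). Because "inspect the dendrogram" is not reproducible, the package
adds an explicit rule: a sample is flagged when its nearest-neighbor
distance exceeds `multiplier` (default 2) times the median nearest-neighbor
distance. The default is conservative — on the simulated fixtures it flags
a genuinely displaced sample and nothing on clean data — and the dendrogram
remains available when a human wants to overrule it. Average linkage was
chosen as the common default for sample-level QC; the linkage is recorded
in the report.

## Numerical choices

* **Degenerate genes.** Zero within-group and zero between-group variation
  gives `f = 0`; zero within-group with positive between-group variation is
  an infinite F, capped at `f_cap = 1e12` so set means and standard
  deviations stay finite. Sums of squares below `n · (1e-10 · rms)^2` are
  treated as zero: without this guard a gene that is constant within groups
  can produce an arbitrary ratio of floating-point rounding errors.
* **Add-one permutation p.** Guarantees `p ≥ 1/(B+1)` and valid coverage.
* **Enumeration fallback.** When `choose(N, size) ≤ n_random`, random-set
  sampling switches to complete enumeration of all subsets — exact, cheaper,
  and the limit the sampled estimator converges to (the same practice as
  exact permutation tests). This only triggers on tiny universes.
* **Degenerate standardization.** If the null scores have zero standard
  deviation (e.g. constant f), the standardized score is defined as 0.
* **Seeds.** Every permutation uses a seed derived deterministically from
  `rng_seed` and the permutation index. Results are therefore bit-identical
  across repeat runs and independent of any chunking of the permutation
  loop across workers (the CLI accepts `--threads` for interface stability;
  execution is sequential).
* **Ties in the result table.** Rows sort by q-value, then pooled p.

## Open design points and the choices made

* **Standardization inside the permutation loop** can redraw random sets
  per permutation (exchangeability-clean; the default) or reuse the
  memberships drawn once per target set, recomputing their scores under
  each permuted statistic (`reuse_random_sets = TRUE`; several-fold
  faster, and on null simulations the two null-score streams agree
  closely). Large calibration and power runs in the test-suite use the
  reuse path.
* **q-values are computed from the pooled p-values** (both p columns are
  reported): the pooled global null is what makes set-to-set comparison,
  and hence a single FDR adjustment, coherent.
* **Set-size filters** (`min_set_size`, `max_set_size`) default to off.
* **Random-set universe**: the full gene universe of the matrix, with no
  expression filter — the weakest defensible reading of "random gene sets
  of the same size", and it keeps the null honest about unexpressed members.
* **Boundary log-fold-changes** in the quadrant classifier (an exact zero
  at either time point) are reported as unclassified rather than assigned
  to an arbitrary quadrant.
* **qPCR efficiencies** are accepted in percent, matching the
  `(1 + E/100)^{-Ct}` convention; values at or below 1 trigger a
  units warning because they look like fractions.

## The simulator

`simulate_counts()` draws `NB(mean = s_j · μ_g · 2^{shift}, dispersion)`
counts: per-gene base means log-uniform on 1–1000 (spanning the bulk of a
bulk-RNA-seq expression distribution), a single common dispersion of 0.1
(a typical bulk-tissue value; configurable), per-sample size factors
uniform on 0.7–1.4, and the study-like default design of 3 groups × 4
samples with ~12,000 genes (a post-exclusion 2/4/3 design is one argument
away). `simulate_gene_sets()` overlays a collection with known truth:
spiked sets receive a log2 group-mean shift (default +1.0 in the last
group, mimicking a late-time-point response) recorded gene-by-gene in the
truth table.

What the simulator emulates: NB counts, library-size variation, coherent
set-level shifts, small n. What it does not: per-gene dispersion trends,
correlation between genes beyond shared set membership, outlier samples
(unless constructed), batch effects, or annotation noise. Passing
calibration and power checks on these simulations therefore demonstrates
the statistical machinery is correct and sensitive under the assumed
generative model, not that any particular biological dataset satisfies that
model.

## Validation scale

The test-suite's statistical checks run at sizes chosen to finish quickly
while keeping Monte-Carlo error small: the type-I-error calibration uses
the full 12,000-gene, 3 × 4-sample design with 200 null sets, 500
permutations and 100 standardization sets (reuse path); the power study
uses 20 replicates of a 2,000-gene universe with 50 sets, one 30-gene set
spiked at +1.0 log2 in one group, 250 permutations. Exhaustive-enumeration
checks (all 90 label assignments of a 2/2/2 design; all subsets of tiny
universes) pin the sampled machinery to exact references.

## Limitations

* The mean-f score is sensitive to a few extreme members; no trimmed or
  max-mean variant is provided.
* No gene-gene correlation is modeled in the standardization null beyond
  what permutation of labels preserves.
* The transform is not a shrinkage rlog/VST; very-low-count genes are
  noisy.
* Differential-expression effect estimates (log fold changes for the
  quadrant classifier) are consumed from upstream tools, not estimated
  here.
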