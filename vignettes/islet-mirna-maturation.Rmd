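---
title: "Inferring direct microRNA targets from paired Ago2-RISC and global mRNA sequencing"
author: "riscmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring direct microRNA targets from paired Ago2-RISC and global mRNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscmir)
```

## The biological problem

Newborn pancreatic beta cells secrete insulin poorly in response to glucose;
the mature, glucose-responsive phenotype is acquired postnatally, around
weaning, together with large coordinated changes in islet microRNA and mRNA
expression. A central analytical question in that setting is which mRNAs are
*direct* targets of the changing miRNAs, as opposed to downstream
(indirect) responders. The experimental design this package analyses answers
it with Argonaute-2 immunoprecipitation: sequencing both the Ago2-bound
("RISC") mRNA fraction and the total ("global") mRNA pool, in control
islet cells and in cells where a candidate miRNA has been overexpressed. An
mRNA recruited into the silencing complex upon miRNA gain is a direct
target; whether its global abundance also falls distinguishes
transcript degradation from translational suppression.

`riscmir` implements that full computational chain — quantification,
filtering, negative-binomial differential expression, cross-fraction target
classification, concordance with the developmental contrast, seed-family and
genomic-cluster organization of the miRNAs, and postnatal time-course
correlation — together with a seeded synthetic generator that emulates the
paired design so that every stage is testable end to end without external
data.

## Abundance units and detection filters

miRNA abundance is expressed as reads per million reads mapped to miRNAs
(RpM); mRNA abundance as fragments per kilobase of exon per million mapped
reads (FPKM). Both are derived display/filter units only: all testing is done
on raw counts.

Two detection filters are applied, with the boundary conventions honoured
strictly as stated:

* a miRNA is "below read cutoff" when **strictly more than** 50% of samples
  have **strictly less than** 10 RpM (`flag_low_mirnas()`; report-driven, the
  matrix is not modified);
* an mRNA is removed when its reads summed over all samples are **strictly
  less than** 1/100,000 of the grand total of the matrix being filtered
  (`filter_low_mrnas()`; rows are dropped, and a per-gene report is
  returned). "Total reads" is the per-dataset grand total, not a per-sample
  quantity.

Both filters are idempotent, and both thresholds are exposed as parameters.
The mRNA filter is applied *before* size-factor estimation in
`run_pipeline()`; applying it afterwards would change size factors only
marginally (the removed tail carries under 0.1% of reads by construction),
but the order is fixed and documented here because it is a genuine degree of
freedom.

## The negative-binomial test

Differential expression follows the classic count-based scheme of the
original DESeq method, deliberately *not* its successor's shrinkage
estimators, because the classic scheme is the one this analysis design used:

1. **Size factors** (`estimate_size_factors()`): for sample $j$,
   $s_j = \mathrm{median}_g \; k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$ over
   genes positive in every sample. The median is the standard arithmetic
   median on the ratio scale (ties averaged), which keeps the estimator
   deterministic and matches a brute-force reading of the definition.
2. **Dispersions** (`estimate_dispersions()`): per gene, a method-of-moments
   estimate from the pooled within-group variance $v$ of normalized counts
   at base mean $m$: $\hat\alpha = \max(0, (v - \bar{s^{-1}} m)/m^2)$ under
   the variance function $\mathrm{Var} = \mu + \alpha\mu^2$; a parametric
   mean–dispersion trend $\alpha(m) = a_1 + a_0/m$ fitted by gamma-family
   regression; and the working value $\max(\hat\alpha, \alpha(m))$ — the
   conservative "maximum sharing" choice.
3. **Test** (`test_differential()`): for each gene the two group sums
   $(K_A, K_B)$ are modelled as negative binomial with means
   $\hat q \sum_{j \in A} s_j$ (resp. $B$) and variances
   $\mu + \alpha \hat q^2 \sum s_j^2$, where $\hat q$ is the pooled
   normalized mean. The two-sided p-value is the probability, conditional on
   $K_A + K_B = k_S$, of all splits no more likely than the observed one.
   When $k_S$ exceeds `exact_limit` (default 5,000) the conditional law is
   replaced by its normal approximation (conditional mean/variance of a
   bivariate normal, continuity-corrected); a test verifies the two agree
   closely across the boundary.
4. **Multiplicity**: Benjamini–Hochberg step-up via `adjust_bh()` (a thin,
   validating wrapper over `p.adjust`; an independent brute-force
   enumeration of the step-up rule is kept in the test suite as the oracle).

Log2 fold changes are computed from normalized group means with a
pseudocount of 0.5 (configurable); the pseudocount exists only to keep the
ratio finite and has no influence on the test.

**Calibration vs conservatism.** The maximum-sharing dispersion rule
deliberately trades power for safety: with 4 replicates per group roughly
half the per-gene estimates sit above the truth, so the end-to-end pipeline
is mildly conservative under the null (the suite checks it stays between
0.5% and 7% rejections at nominal 5%). The calibration test proper is
therefore run on `test_differential()` with the model dispersion supplied,
which isolates the conditional test from the estimator; there it is
accurate (empirical type-I error 0.05 ± 0.02 in the packaged simulation,
with ≥ 90% power at p < 0.001 for 4-fold effects at mean 100 and
$\alpha = 0.05$).

## Signed fold-change tables

Microarray-style tables report linear folds with the negative-reciprocal
convention: `signed_fold_change(ref, alt)` returns $2^{\Delta}$ for
$\Delta \ge 0$ and $-2^{-\Delta}$ otherwise, so $-4.2$ means 4.2-fold lower.
Display rounding is half-away-from-zero to one decimal
(`round_half_away()`), since banker's rounding would not reproduce printed
tables. The packaged reference table of 17 selected miRNAs
(`load_table1_fixture()`, `check_table1_fixture()`) recomputes every row
from its two log2 group means to within ±0.1 fold; rows where two-decimal
rounding of the published means shifts the last printed digit are flagged
separately rather than forced to match. Selection of "changed" features uses
the inclusive rule $|fc| \ge 2$ and $q \le 0.05$ (`select_changed()`), both
thresholds exposed.

## Seed families, genomic clusters, seed matching

The seed is defined as nucleotides 2–8 of the mature miRNA (7 nt) — the
standard convention in miRNA biology; the analysis this package supports
never states the length numerically, so the choice is documented here as a
package decision. Families are the exact partition by seed identity
(`group_families()`); ids are the lexicographically smallest member, making
assignment order-invariant. Clusters chain loci on one chromosome and strand
by single linkage with a 10 kb default gap (`group_clusters()`) — a
polycistron heuristic exposed as `max_gap_bp`, not a biological claim. GFF3
input is 1-based inclusive; gaps are measured on the 0-based half-open scale
at the module boundary, avoiding mixed-convention off-by-ones.
`scan_seed_matches()` finds 7mer-m8-style reverse-complement seed sites,
including overlapping ones; it exists to verify planted synthetic truth and
is intentionally not a target predictor (no wobble pairs, no context or
conservation scores).

## Direct-target classification and concordance

`classify_direct_targets()` implements the cross-fraction rule: a call
requires a significant RISC increase (`risc_q <= fdr`, positive log2 fold
change; default FDR 0.1). The mode is *degradation* when the global fraction
also decreases significantly, *translational suppression* when the global
change is not significant. Three decisions deserve emphasis:

* genes with a significant global **increase** satisfy neither admissible
  outcome and are excluded, with a reason code, rather than silently dropped
  or force-labelled;
* "no significant change" is operationalized purely as `global_q > fdr`,
  with no effect-size ceiling — a liberal reading, stated as such;
* no minimum RISC fold change is imposed beyond significance
  (`min_risc_lfc = 0`, configurable).

Calls are monotone in the FDR parameter and the two modes partition the call
set by construction.

`concordance_with_development()` compares each perturbation-responsive gene
(by sign of its log2 fold change, regardless of magnitude) with the
developmental adult-vs-P10 contrast and tabulates
opposite-significant / opposite-nonsignificant / concordant classes with
integer-rounded percentages. The responsive universe is explicitly
intersected with the developmental gene list; genes absent from it are an
error, not a silent drop.

## Postnatal time course

`correlate_pairs()` computes Pearson correlation between a miRNA and a
candidate target across the postnatal grid (default P10, P15, P20, P23,
P31, adult), with p from the t-distribution on $n-2$ df. The methods
language this design descends from mixes "Pearson" and "rank" terminology;
Pearson on values is implemented as the primary method because the more
specific figure-level description says Pearson, and `method = "spearman"` is
provided as the escape hatch. Default pairing averages replicates within
timepoints (`per-timepoint-mean`, $n$ = number of timepoints);
`per-animal` pairing by replicate id is available when replicates are
matched.

`earliest_change_timepoint()` locates the first timepoint differing from the
reference by Welch t-tests with Bonferroni correction across the
non-reference timepoints. This replaces a one-way ANOVA with Dunnett
post-hoc comparison: the operation is a descriptive locator on synthetic
trajectories, and the Bonferroni-Welch combination is slightly conservative
relative to Dunnett, which only strengthens the recovery guarantees it is
used for. It is monotone in `alpha` by construction.

## The synthetic generator

`simulation_config()` fixes the study conditions; the defaults are the
generator's definition of the design, not tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| `n_mrnas` | 5,000 | post-filter mRNA universe (a few thousand genes) |
| `n_mirnas` | 300 | ~300 detected miRNAs |
| `n_per_group` | 4 | 3–4 biological replicates |
| `nb_dispersion` | 0.05 | bulk RNA-seq biological variability |
| library sizes | lognormal, $\mu = \ln 2\times10^6$, $\sigma = 0.25$ | non-trivial size factors |
| planted \|log2fc\| | uniform on [1, 2] | 2–4-fold direct-target effects |
| planted targets | 100 degradation + 100 suppression | the two regulation modes |
| `n_developmental_de` | 600 | adult-vs-P10 regulated genes, half up/half down |
| timepoints | P10…adult, change at P23 | the peri-weaning transition window |
| `r_true` | −0.9 | replicate-level miRNA/target anticorrelation |

Baseline relative abundances are log-normal (sdlog 1.2), which leaves the
1/100,000 filter removing only a ~2–3% low-abundance tail (the suite checks
the default design keeps ≥ 4,800 of 5,000 genes). Degradation plants get
$+\mathrm{lfc}$ in RISC and $-\mathrm{lfc}$ globally; suppression plants get
$+\mathrm{lfc}$ in RISC and exactly 0 globally — clean separation, so
mode-confusion measurements are attributable to the classifier, not to
ambiguous truth. Plants are drawn from genes above the detection filter
(baseline share ≥ 5×10⁻⁵): the classification operates on detected genes,
and planting effects in the censored tail would measure the filter rather
than the classifier.

For the time course, each planted miRNA follows a unit step at the change
timepoint and its target the mirrored step; Gaussian replicate noise is
solved analytically from `r_true` via
$\sigma^2 = \mathrm{var}(\mathrm{traj})\,(1/|r| - 1)$, which also makes the
step amplitude ≈ 6 replicate SDs — consistent with the well-separated
trajectories the recovery tests assume. Averaging 4 replicates per timepoint
therefore estimates a correlation stronger than `r_true`, which is what the
per-timepoint-mean invariant measures. With `r_true = 0` the target is flat
noise; the null sampling density of $r$ on 6 points is
$\propto (1-r^2)$, giving $E|r| = 3/8$ exactly, and the suite tests the mean
absolute null correlation against that closed form.

Annotation generation plants genomic clusters of 2–5 members (intra-cluster
gaps 0.2–5 kb, clusters megabases apart) and unique seeds except for one
family deliberately spanning two clusters — the paralogous-polycistron
situation — so that family and cluster recovery are distinguishable.

All generators set the full RNG state (Mersenne-Twister / inversion /
rejection sampling) from the config seed plus a per-generator offset, so
outputs are reproducible across platforms and independent of call order.

### What the generator does not emulate

No GC or length bias, no batch effects, no mean-dependent dispersion trend
(available as an option but off by default), no partial repression in the
suppression mode, no indirect (secondary) targets, no raw reads. Passing the
recovery tests therefore demonstrates that the statistical machinery is
correct under the stated model — not that real immunoprecipitation data,
with its cross-linking artefacts and background binding, would yield the
published target counts. Reproducing those (113 direct targets; 309
responsive mRNAs with 60%/21% concordance splits; 311 detected miRNAs)
requires the deposited raw data and is expressly out of scope.

## Problem sizes and numerical choices

The test suite runs the full default design (5,000 genes × 16 samples for
the paired fractions, exact tests throughout) in well under a minute; the
calibration simulations use 2,000 genes, and structure/time-course checks
use the default 300 miRNAs and 50 trajectory pairs. Degenerate inputs are
errors, not silent results: zero-read libraries, all-zero normalization
references, sub-3-point correlations, zero-variance series, universe
mismatches. Genes with zero counts in both contrast groups are reported as
`not_tested` with p = 1 and q = `NA`. Ties in the size-factor median average
the two central ratios; the BH wrapper validates its domain before
delegating.

## Known limitations

* The exact conditional test loops over genes in R; at count sums beyond
  ~10⁵ per gene the normal fallback governs runtime and accuracy.
* The dispersion trend is the two-parameter $a_1 + a_0/m$ family; datasets
  with strongly non-monotone mean–dispersion relations would be served
  poorly (the conservative max-sharing rule bounds the damage).
* `earliest_change_timepoint()` controls the family-wise error per feature,
  not across features; a genome-wide scan should correct externally.
* qPCR relative expression assumes perfect doubling efficiency (classic
  delta-delta-Ct); efficiency-corrected models are out of scope.
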