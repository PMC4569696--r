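# riscmir

MicroRNA target inference from paired Ago2-RISC / global mRNA sequencing,
and analysis of postnatal pancreatic-islet maturation.

## The problem

Pancreatic beta cells acquire glucose-stimulated insulin secretion
postnatally, around weaning, alongside sweeping changes in islet microRNA
expression. Deciding which mRNAs are *direct* targets of a changing miRNA —
rather than downstream responders — is the core analytical problem. The
design this package implements answers it by sequencing two mRNA pools from
the same cells, with and without overexpression of the candidate miRNA:

* the **RISC fraction** — mRNAs co-immunoprecipitated with Argonaute-2,
  i.e. engaged by miRNA-loaded silencing complexes;
* the **global fraction** — the total mRNA pool.

A direct target shows a significant abundance **increase in the RISC
fraction** upon miRNA gain. Its global behaviour assigns the mode of
regulation:

| RISC fraction | global fraction | call |
|---|---|---|
| up (q ≤ 0.1) | down (q ≤ 0.1) | direct target, transcript **degradation** |
| up (q ≤ 0.1) | no significant change | direct target, **translational suppression** |
| up (q ≤ 0.1) | up (q ≤ 0.1) | excluded (matches neither admissible outcome) |

Differential expression uses the classic count-based negative-binomial
scheme: median-of-ratios size factors, method-of-moments dispersions with a
fitted mean–dispersion trend and conservative `max(raw, fitted)` sharing, an
exact conditional test on the two group sums (normal fallback for large
totals), and Benjamini–Hochberg adjustment. Around that core the package
provides RpM/FPKM quantification with the strict low-abundance filter
boundaries ("more than 50% of samples below 10 RpM"; "less than 1/100,000
of total reads"), signed fold-change tables with the negative-reciprocal
convention, miRNA seed-family (seed = nt 2–8) and genomic-cluster (10 kb
single linkage) organization, concordance of perturbation-responsive genes
with the developmental adult-vs-P10 contrast, postnatal time-course
correlation, delta-delta-Ct qPCR folds, and a fully seeded synthetic
generator emulating the whole design.

## Worked example

Simulate the default paired design (5,000 mRNAs, 100 planted
degradation-mode and 100 suppression-mode targets, 4 replicates per group,
NB dispersion 0.05), filter, fit both fractions, and classify:

```r
library(riscmir)

cfg <- simulation_config(seed = 42)
sim <- generate_paired_fraction_counts(cfg)

fg <- filter_low_mrnas(sim$global)
fr <- filter_low_mrnas(sim$risc)
universe <- intersect(rownames(fg$counts$counts), rownames(fr$counts$counts))
gcm <- count_matrix(fg$counts$counts[universe, ], fg$counts$sample_meta)
rcm <- count_matrix(fr$counts$counts[universe, ], fr$counts$sample_meta)

fit_r <- nbde(rcm, contrast = c("control", "mirOE"))
fit_r
#> Negative-binomial differential expression: mirOE vs control
#> 4849 genes tested; at FDR 0.1: 199 up, 9 down

fit_g <- nbde(gcm, contrast = c("control", "mirOE"))
out <- classify_direct_targets(fit_r$results, fit_g$results, fdr = 0.1)
table(out$calls$mode)
#>               degradation translational_suppression
#>                        93                       106

head(out$calls, 3)
#>    gene_id                      mode risc_log2fc       risc_q global_log2fc     global_q
#> 1 gene4515 translational_suppression    2.314848 2.120829e-16     0.1906808 1.000000e+00
#> 2 gene2839 translational_suppression    2.171322 1.819862e-14     0.2752959 1.000000e+00
#> 3 gene0901               degradation    2.068474 6.796490e-14    -1.5841630 1.872143e-07
```

The 199 calls recover 97–98% of the 200 planted targets with an empirical
false-discovery proportion of 2% (the truth table is in `sim$truth`). The
RISC fold change is positive for every call; the global column separates the
two modes. Signed microarray-style folds use the negative-reciprocal
convention:

```r
signed_fold_change(8.01, 5.94)   # log2 means: reference, alternative
#> [1] -4.198867                  # i.e. 4.2-fold lower
```

`run_pipeline(pipeline_config(...))` chains every stage (filters, three DE
fits, fold-change selection, target classification, concordance, time-course
correlations, miRNA organization) over a fixture tree written by
`write_synthetic_dataset()` and returns a per-stage report.

## Layout

* `R/` — implementation: I/O and validation, quantification/filters, the NB
  test, fold-change tables, miRNA organization, RISC classification,
  concordance, time course, synthetic generator, pipeline.
* `tests/testthat/` — unit, property and end-to-end recovery tests (all
  fixtures generated in code or packaged as small TSV).
* `vignettes/islet-mirna-maturation.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, limitations.
* `scripts/acceptance.R` — see above.
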