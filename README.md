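# chromstrat

Unsupervised chromatin-accessibility stratification of tumor cohorts, with a
fully planted synthetic cohort for verification.

Tumor subgroups that are invisible to expression-based classification can
separate cleanly in ATAC-seq accessibility. `chromstrat` implements that
workflow end to end: per-tumor peak calls are merged into a union region
set, each tumor's signal is scored over the union and rank-normalized, the
tumors are embedded (UMAP, `n_neighbors = 10`) and clustered into chromatin
groups, and each group's **signature** — regions with group-vs-rest
log2 fold change > 2.5 (pseudo-count 1) — is called on the raw scale.
Signatures are annotated (TSS distance, CpG density, genes within 1 Mb),
scanned for transcription-factor motifs (PWM log-odds, both strands), and
tested for motif enrichment against size-matched background regions
(binomial tail on region hit fractions). Downstream associations link motif
accessibility to tumor stage (one-tailed Welch t-tests across stage pairs),
couple regulator expression to accessibility (Pearson), deplete Basal-like
tumors via a FOXA1/GATA3 bottom-quartile filter, and build top/bottom-decile
expression tables for gene-set enrichment.

Because every one of those steps is a claim about recoverable structure, the
package ships a generator (`cohort_spec()` / `generate_cohort()`) that
plants all of it — groups, near-closed group-private signature regions,
motif occurrences at signature and background rates, a stage-graded
accessibility program, and a regulator gene anticorrelated with it through a
Gaussian copula — and records the truth for evaluation. See the vignette
(`vignettes/chromatin-stratification-methods.Rmd`) for the model and every
parameter choice.

## Worked example

```r
library(chromstrat)

co <- generate_cohort(cohort_spec(seed = 1))        # 5000 regions x 60 tumors
ranks <- rank_normalize(co$accessibility)
strat <- stratify_tumors(ranks, seed = 1)           # UMAP + k-means, k = 3
table(strat$groups$group)
#>  1  2  3
#> 20 20 20

sigs <- call_signatures(co$accessibility, strat$groups)
vapply(sigs, nrow, 0L)
#>   1   2   3
#> 200 200 200
```

Running the full driver chain (`analysis/01_simulate.R` …
`analysis/06_associations.R`) from the written primary files reproduces the
planted structure through the union-peak path: group recovery ARI = 1
against the planted labels, and the motif enrichment table

```
 motif signature   fold          p stars
   SOX         1  13.49  9.3e-156   ***
   FOX         2   2.03   3.3e-32   ***
  CEBP         3  15.37  1.0e-164   ***
```

with all off-diagonal motif/signature pairs at fold < 0.1. The planted FOX
stage trend comes out at p ≈ 1.3e-05 for every adjacent stage pair
(I→II 9.98 → 12.83, II→III → 15.63, III→IV → 18.43; extreme pair
p ≈ 2.7e-15), SOX and CEBP stay flat (p ≈ 0.4), and ANP32E expression
anticorrelates with FOX-region accessibility (r = −0.41, p = 0.0013). The
FOXA1/GATA3 bottom-quartile filter removes 11 of 60 tumors, all of them from
the planted basal-like group.

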