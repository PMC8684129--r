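---
title: "Methods: chromatin-accessibility stratification of a synthetic tumor cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-accessibility stratification of a synthetic tumor cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromstrat` implements an end-to-end chromatin-accessibility stratification
workflow for a tumor cohort — union peak sets, rank normalization, embedding
and clustering into chromatin groups, group-private signature calling, motif
scanning and enrichment, and downstream clinical associations — together with
a synthetic cohort generator that plants every effect the analysis is meant
to recover. This vignette documents the statistical model, the parameter
choices, what the generator does and does not emulate, and the numerical
conventions.

## 1. The analysis model

### 1.1 Regions and the accessibility matrix

All external coordinates are 0-based half-open (BED convention); internally
regions live in `GRanges` (1-based closed) and conversion happens only at the
IO boundary (`region_set()`, `write_bed()`).

When starting from primary files, `merge_peaks()` forms the union of the
per-tumor peak calls (book-ended intervals merge), and `score_regions()`
assigns each tumor's signal to each union region as the length-weighted mean
of its coverage track over the region, with uncovered bases contributing 0.
`build_accessibility_matrix()` assembles the region × tumor matrix.

### 1.2 Rank normalization and stratification

Accessibility distributions differ across tumors in depth and dynamic range,
so comparisons across tumors use within-tumor ranks: `rank_normalize()`
replaces each column by its ranks with average ties (`ties.method =
"average"`), making every tumor's marginal distribution identical.

`embed_samples()` reduces the rank matrix to two dimensions. The default
reducer is UMAP (`uwot`, `n_neighbors = 10`, single-threaded with SGD
disabled so the embedding is reproducible given the seed). A deterministic
classical-MDS reducer (`method = "mds"`) is provided behind the same
contract; it is useful when exact coordinate-level reproducibility across
platforms matters more than UMAP's local structure.

`assign_groups()` runs k-means (k = 3 by default, `nstart = 25`) on the
embedding and relabels clusters by decreasing separation along the second
embedding dimension, so group labels are a deterministic function of the
geometry rather than of k-means' internal ordering. Group labels are still
arbitrary with respect to any external labeling; recovery evaluation uses the
adjusted Rand index and greedy label matching (`match_groups()`).

### 1.3 Chromatin signatures

A group's signature is the set of regions whose group-vs-rest log2 fold
change, computed on the raw (not rank) scale with a pseudo-count of 1,

\[ \mathrm{log2FC} = \log_2\frac{\bar a_{\text{in}} + 1}{\bar a_{\text{out}} + 1}, \]

strictly exceeds 2.5. The pseudo-count bounds the statistic for regions that
are closed outside the group; the strict threshold means a region at exactly
2.5 is excluded. Note the consequence: a region whose accessibility is merely
`signature_effect`-fold higher inside the group but at baseline elsewhere can
never exceed `log2(signature_effect)`; signatures in this model are
group-private regions that are *nearly closed* in all other tumors, which is
also how the generator plants them (§2.1).

### 1.4 Region annotation and background sampling

Signature regions are annotated with the distance from their midpoint
(`floor((start + end) / 2)`) to the nearest TSS, their CpG dinucleotide
density, and the genes whose TSS lies within 1 Mb (inclusive) of the
midpoint. Motif enrichment needs a background matched to the signatures'
length distribution: `sample_background()` splits the targets into length
deciles and draws each stratum's share from peaks whose lengths fall in the
same stratum, without replacement, deterministically given the seed. If the
target lengths are (near-)constant the target deciles degenerate, and
stratification falls back to the peak-length deciles so draws stay inside
the stratum containing the target length.

### 1.5 Motif scanning and enrichment

`scan_motif()` scores every window of motif width on both strands with the
PWM log-odds against a background base distribution (uniform by default); a
window is a hit when its score reaches `score_fraction` (default 0.8) of the
maximal attainable score. Windows containing `N` never hit. Consensus strings
become sharp PWMs (0.991 on the consensus base, 0.003 elsewhere), for which
the 0.8 threshold admits exact matches only. Reverse-complement-palindromic
motifs necessarily report a + and a − hit over the same interval; this is a
property of any both-strand scanner, not an artifact.

`motif_enrichment()` compares the fraction of target regions containing at
least one hit with the background fraction, reporting the fold ratio and the
upper binomial tail `P(X ≥ k_t | n_t, p_bg)`. When the background has zero
hits the rate is floored at `1 / (2 n_bg)` so the p-value stays defined.

### 1.6 Downstream associations

Per-tumor motif accessibility is the mean accessibility over the *distinct*
regions carrying the motif. Stage trends are one-tailed Welch t-tests between
all adjacent stage pairs plus the extreme (first vs last) pair, in the stated
direction, annotated with stars at p < 0.01 / 0.001 / 0.0001 (strict).
Expression–accessibility coupling uses the Pearson correlation with its
two-sided t-based p-value. The marker filter removes tumors at or below the
type-7 bottom-quartile cut of *both* FOXA1 and GATA3 expression (the
boundary rule is configurable), a standard device for depleting Basal-like
tumors from an expression cohort. `decile_tables()` sorts samples by one
gene's expression (ties broken by sample id) and returns per-gene mean
expression in the top and bottom `floor(n/10)` samples — the input a
gene-set enrichment analysis consumes.

## 2. The synthetic cohort generator

Defaults (`cohort_spec()`) are the package's standard study conditions:
3 groups × 20 tumors, 5,000 accessible regions, 200 signature regions per
group. They were chosen once, for desk-scale runtimes, before any outcome
was inspected, and are not tuned to any particular analysis result.

### 2.1 Accessibility

Ordinary open regions have mean accessibility `baseline_mean = 10` in every
tumor. Each group owns 200 signature regions with mean
`baseline_mean × signature_effect = 40` inside the group and
`baseline_mean × closed_fraction = 1` outside — near-closed chromatin, per
the model in §1.3. Observed values are the means times lognormal
multiplicative noise with `sdlog = 0.25` and `meanlog = −sdlog²/2`, so the
noise is mean-preserving.

### 2.2 Motif families

Each family (SOX → group 1, FOX → group 2, CEBP → group 3) is planted in 80%
of its group's signature regions *and* in a fraction of the non-signature
background (FOX 39%, others 5%). The background fraction matters twice:
enrichment of a family in its signature is only a non-trivial statement when
the motif also occurs elsewhere, and the stage trend (below) is computed
over all FOX-bearing regions, most of which must lie outside the group-2
signature or the stage comparison would be hopelessly confounded by group
membership. The consensus string (or its reverse complement, with equal
probability) is written into each carrier region of the genome at a random
offset; the genome is drawn last so that skipping its emission
(`emit = character(0)`) leaves all statistical layers byte-identical.

### 2.3 Stage trend and regulator coupling

Tumor stages I–IV cycle within groups, so stage is balanced across groups by
construction. FOX-carrier regions get an additive increment
`stage_effect × (stage_index − 1)` — stage I is the un-shifted reference.
The regulator gene ANP32E is coupled to mean FOX-carrier accessibility
through a Gaussian copula on ranks: with `z` the normal score of a tumor's
rank, expression is built from `ρ z + √(1−ρ²) ε` with target correlation
`ρ = −0.5`. The copula fixes the target correlation without constraining
either marginal. FOXA1 and GATA3 are drawn lognormal with higher location in
the two luminal-like groups, which is what gives the quartile filter
something real to remove.

### 2.4 What is and is not emulated

Emulated: group-private near-closed signature chromatin, motif occurrence at
both signature and background rates, a stage-graded accessibility program,
regulator anticorrelation, per-sample peak-call jitter, and stage/PAM50/IHC
metadata correlated with the groups. Not emulated: read-level counts and
depth variation (signal is continuous), GC/mappability bias, chromatin
domains and spatial autocorrelation between neighboring regions, copy-number
effects on accessibility, and realistic genome composition (background
sequence is uniform i.i.d.). Conclusions about methods that depend on those
properties cannot be drawn from this generator.

## 3. Numerical conventions

- Pseudo-count 1 on both means of every log2 ratio; thresholds are strict
  (`>`), so boundary values are excluded.
- Quantiles are type-7 (R's default) everywhere a cut is computed; the
  quartile filter removes at `≤` the cut by default.
- Welch (unequal-variance) t-tests throughout; when both samples are
  constant and equal the one-sided p is defined as 0.5.
- All randomness flows from a single integer seed per entry point; derived
  seeds stay below 2³¹. The same spec and seed reproduce every written file
  byte-identically.
- Rank normalization uses average ties, so each column of the rank matrix
  sums to `n(n+1)/2`.

## 4. Problem sizes

The standard cohort (60 × 5,000, with genome) generates in a few seconds;
motif scanning over its ~1.4 Mb genome dominates a full pipeline run
(~45 s). The regulator-coupling sweep uses 100 cohorts of 100 tumors with
1,000 regions and 40 signatures per group — the correlation estimator does
not depend on region count, and the reduced size keeps 100 replicates within
a desk-scale run budget. These sizes are the package's own choices for
keeping the full test suite and the analysis scripts runnable in minutes on
one core.

## 5. Running the workflow

```{r}
library(chromstrat)

co <- generate_cohort(cohort_spec(seed = 1))
ranks <- rank_normalize(co$accessibility)
strat <- stratify_tumors(ranks, seed = 1)
sigs <- call_signatures(co$accessibility, strat$groups)
```

The numbered scripts under `analysis/` run the same pipeline from the
written primary files (peaks + tracks → union → matrix) and leave all
tables under `results/`.
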