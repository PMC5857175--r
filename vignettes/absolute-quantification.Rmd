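---
title: "Absolute microbiome quantification with absquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute microbiome quantification with absquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absquant)
library(dplyr)
```

## The problem

Amplicon sequencing reports *relative* abundances: each taxon's fraction of
the reads in its sample. Because the fractions of every sample sum to one, a
taxon's share can rise while its actual population collapses — it only has
to collapse more slowly than the rest of the community. Any statement about
whether a taxon *grew* needs an absolute scale.

`absquant` implements the integrated quantification approach that supplies
that scale: the total bacterial 16S rRNA gene load of a sample, `T` (copies
per gram of dry soil), is measured by qPCR, and each taxon's absolute
abundance is

$$A_i = p_i \times T,$$

where `p_i` is its relative abundance from sequencing of the same 16S
variable region. The result is in 16S gene copies per gram; dividing by a
taxon's rRNA operon count `c_i` gives genome (≈ cell) equivalents,
`G_i = A_i / c_i`.

### Assumptions

The multiplication rule assumes that (i) the qPCR primers and the
sequencing primers target the same marker in the same region, so `T` and
the `p_i` describe the same pool of molecules; (ii) extraction,
amplification and classification biases act proportionally across taxa
within a sample; and (iii) per-sample read depth is large enough that `p_i`
is a stable estimate. None of these is exactly true in real soil — which is
why the package ships the spike-in validation machinery rather than taking
the rule on faith.

## The pipeline

1. **Calibration** — `fit_standard_curve()` regresses Ct on log10(copies)
   over a plasmid dilution series. The slope determines amplification
   efficiency `E = 10^(-1/slope) - 1` (−3.32 cycles/decade ⇔ 100%); the
   mean Ct of the most dilute standard becomes the limit-of-quantification
   Ct.
2. **Quantification** — `qc_quantify()` interpolates the mean of replicate
   Ct values on the curve (quantifying from the mean Ct, not the mean of
   per-replicate copies, the conventional delta-Ct reading) and flags
   replicate SD above 0.5 cycles, means beyond the LoQ Ct (non-detects),
   and extrapolation outside the standard range. `copies_per_gram()`
   rescales by the extraction geometry (template volume, eluate volume,
   soil mass).
3. **Integration** — `to_relative()` and `integrate_abundance()` apply
   `A_i = p_i × T`. Totals from different 16S regions (V3, V4) are never
   averaged: each region yields its own table, because the two regions'
   primer pools quantify measurably different totals and V4 is generally
   the more faithful one. When triplicate extractions are pooled into one
   sequencing library, the matching `T` is the mean of the triplicate qPCR
   totals.
4. **Validation** — `validate_spikein()` checks the whole chain against an
   internal-reference strain of known addition carrying a known-copy
   marker gene, and `compare_methods_anova()` runs the
   Levene → Tukey/Tamhane agreement test per treatment.
5. **Dynamics** — `count_discordant()` classifies every taxon's pair of
   changes between two time points, and `cluster_samples()` orders samples
   for heatmaps.

## Parameters that matter

| parameter | where | default | rationale |
|---|---|---|---|
| `sd_limit` | `qc_quantify()` | 0.5 cycles | replicate scatter above half a cycle (≈ 1.4× in copies) makes the triplicate mean unreliable |
| `threshold` | `pool_minor()` | 0.001 | the usual 0.1% display cut-off; strict `<`, and a taxon is pooled only if below the cut-off in **every** sample, so no taxon is split between its own label and "Minor" across a figure |
| `ratio_16s_to_marker` | `expected_marker_copies()` | — | strain genomics: 7 for a strain with 7 rRNA operons and a single-copy marker |
| `default_c` | `to_genome_equivalents()` | 1 | leaves taxa without a known operon count uncorrected (with a warning) instead of guessing a community-wide value |
| `eps` | `classify_trend_pair()` | 0 | strict sign test; raise it when read-count noise makes tiny deltas meaningless |
| `slope_range`, `r2_min` | `validate_spikein()` | [0.9, 1.1], 0.99 | a quantification that cannot track a 5-decade dilution series within 10% of slope 1 should not be trusted |
| `transform`, `linkage` | `cluster_samples()` | log10(x+1), complete | the common heatmap defaults for quantities spanning orders of magnitude |

## Numerical and design choices

* **Two R² conventions.** For through-origin fits the centered and
  uncentered coefficients of determination differ, and published agreement
  plots rarely say which they use. `fit_validation_regression()` always
  reports both, labelled; the pass/fail verdict in `validate_spikein()`
  uses only the centered R² of the with-intercept calibration fit, where
  the conventions coincide.
* **Non-detect logic.** A sample whose mean Ct exceeds the most dilute
  standard's Ct is flagged `below_loq` rather than assigned a copy number
  of zero — the signal may be real but cannot be distinguished from
  primer artefacts, which is exactly how an unspiked control soil reads
  for a spike-specific marker.
* **Drop-lowest agreement fit.** The spike treatment nearest the
  sequencing detection limit is dominated by misclassification carry-over
  (reads assigned to the spike genus that are not the spike strain), so
  the through-origin agreement regression is reported with and without it.
* **Tamhane's T2** is implemented as pairwise Welch t statistics with
  Welch–Satterthwaite degrees of freedom and Šidák adjustment, the
  standard construction; Levene's test uses mean centering. The compact
  letter display uses the insert-and-absorb algorithm, processing groups
  in decreasing-mean order so the lettering is invariant to row order.
* **Aggregation keys.** `aggregate_by_rank()` groups by the full rank path
  (domain…rank), not the bare rank name, so homonymous genera in
  different families never merge; taxa unclassified at the target rank are
  collected under `"Unclassified"` per their deepest classified prefix.
* **Degenerate inputs.** Single qPCR replicates get SD 0 (no SD flag);
  zero-total sequencing samples are an error, not NaNs; a taxon appearing
  from absolute zero is classified as an increase but its percent change
  is reported as undefined (`NA`), never infinity.
* **Detection limit.** `detection_limit()` reports
  `L = (min_reads/depth) × T` exactly and leaves rounding to orders of
  magnitude to the caller; with 5 reads at depth 66,460 and
  `T = 1e8`–`1e10` copies/g, `L` spans roughly `7.5e3`–`7.5e5` copies/g.

## What the synthetic generator emulates — and what it does not

`synth_experiment()` generates a complete study with known truth: a fixed
background community (one Dirichlet draw, `α = 0.5`, the long-tailed
few-dominants shape of soil), lognormal background totals (median
`5.82e9` copies/g, log10-SD 0.0246, matching a ~6% CV between extraction
replicates), a spike strain added at `7e9`–`7e4` genomes/g with 7 rRNA
operons and a single-copy marker, multinomial sequencing at 66,460
reads/sample, and triplicate qPCR with 0.05-cycle Gaussian Ct noise around
a 100%-efficiency curve. Sub-seeds per component keep the qPCR noise
stable when the community size changes.

It deliberately does **not** model sequencing error, chimeras,
misclassification, primer bias, or extraction efficiency differences —
counts are ideal multinomial draws. Passing recovery tests therefore
demonstrate that the *computational* chain is unbiased and converges at
the multinomial rate; they say nothing about wet-lab biases, which is what
the real spike-in experiment is for. Test problem sizes (10–30 taxa,
depths of 10⁴–10⁷, ≤100 replicate simulations) were chosen as the smallest
sizes at which the binomial-error bounds being asserted are sharp.

## Worked example

```{r example}
v <- validate_spikein(edl933_spikein(), copy_ratio = 7)
tidy(v)
glance(v)
```

The calibration fits (marker vs nominal addition) recover slope ≈ 0.97
with centered R² ≈ 0.999 in both regions; the through-origin agreement
fits between the qPCR expectation and the sequencing-derived estimate sit
within 3% of slope 1, and dropping the detection-limit treatment improves
them further.

```{r detection}
detection_limit(5, 66460, 1e8)$limit
```

## Known limitations

* No community-wide 16S copy-number correction: `to_genome_equivalents()`
  corrects only taxa you supply counts for. rrnDB-style inference is out
  of scope.
* The method inherits qPCR's sensitivity to inhibitors and primer
  coverage; a biased `T` scales every `A_i` by the same factor.
* Discordance classification at `eps = 0` treats any sign flip as
  discordant, including flips well within sampling noise; choose `eps`
  with the read depth in mind.
* Heatmap clustering is deterministic but metric-dependent; the defaults
  mirror common practice, not an optimality claim.
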