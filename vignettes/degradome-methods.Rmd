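---
title: "Methods: degradome tag analysis of mRNA stability, cleavage and decapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degradome tag analysis of mRNA stability, cleavage and decapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model and procedural choices behind
`parecall`, in the order the pipeline applies them. The package analyzes
two kinds of 5′-end tag libraries against a transcript annotation:

* **PARE** tags mark the 5′ termini of 5′-monophosphorylated RNA decay
  intermediates (the degradome). In an XRN1-depleted background these
  intermediates accumulate, so tag abundance reads out decay flux.
* **C-PARE** tags mark the 5′ ends of *capped* transcripts and locate the
  empirical cap position.

All experiments in this package are synthetic: a seeded generator plants
known stability classes, cleavage sites and decapping events, so every
downstream claim can be checked against ground truth.

## 1. Tag standardization and filtering

Raw reads are reduced to 20-nt tags (`trim_reads`): the 3′ adapter is
removed at its leftmost occurrence (a truncated adapter at the read end
needs ≥ 3 nt of overlap), reads shorter than 20 nt after trimming are
discarded, and longer inserts are truncated to their first 20 nt — the tag
is the 5′ end, which is the biologically meaningful coordinate.

Three filters follow (`filter_tags`), each strictly shrinking the tag set:

1. **Simple sequence repeats.** A tag is removed when any 12-nt window is a
   perfect period-1, -2 or -3 repeat. The implementation reduces this to a
   run of ≥ 12 − p consecutive matches in the lag-p self-comparison, which
   vectorizes over whole libraries; its agreement with a brute-force
   window/period enumeration is part of the acceptance suite.
2. **Genomic multi-hits.** Tags matching more than 20 genomic loci at up to
   one mismatch (both strands) are removed as unmappable repeats.
3. **Mitochondrial tags.** Tags matching the mitochondrial contig exactly
   (either strand) are removed; mitochondrial turnover is outside the
   model.

Surviving tags are assigned to every (transcript, position) whose 20-nt
cDNA substring is within Hamming distance 1 (`map_tags`). A tag shared by
several isoforms contributes its full count to each, but each read is
counted once in the library total. Matching uses a split-seed 10-mer
index: any 20-mer within one mismatch of a target shares at least one
exact 10-mer half with it, so candidate positions come from two exact
half-lookups and are then verified. `N` bases never match, so they count
as mismatches.

## 2. Normalization

* **RPM** — tag count × 10⁶ / (reads with ≥ 1 hit in the relevant
  reference). The denominator deliberately excludes unmapped reads so that
  per-position abundances sum to 10⁶ over each library.
* **DPKM / FPKM** — count × 10⁹ / (cDNA length × library total), the same
  formula applied to degradome tag sums (DPKM) and RNA-seq fragment counts
  (FPKM). Using one formula for both makes their ratio a unitless relative
  stability measure.

## 3. Stable / unstable classification

For each transcript the two RNA-seq replicates are compared against the
two PARE replicates with an exact conditional count test
(`exact_count_test`). Counts are scaled to the geometric mean of the
library sizes and pooled; conditional on the pooled total $t$, the RNA-seq
count under the null follows

* binomial $(t, 1/2)$ when the common dispersion is 0, or
* the conditional law of one negative-binomial count given the sum of two
  i.i.d. counts (a negative hypergeometric, free of the unknown mean)
  when the dispersion is positive.

The two-sided p-value sums the probabilities of all outcomes no more
likely than the observed one. The common dispersion is estimated by the
method of moments on library-size-scaled replicate counts
(`estimate_dispersion`), pooled over both assays. The test is
independently validated in the test suite against direct binomial
enumeration and against `edgeR::exactTest`, which implements the same
conditional test; `edgeR` is never used in the implementation itself.

**Composition correction.** Library-size normalization alone is biased
when the planted (or real) fraction of differentially degraded transcripts
is large: a 20%/20% split at ±4 log₂ shifts every naive log-ratio by
almost 2 units. The test therefore uses *effective library sizes*: the
raw sizes are rescaled by the median log-ratio between pooled RNA-seq and
pooled degradome relative abundances (a median-of-ratios size factor), so
the typical transcript is balanced. Under a balanced null this reduces to
plain library-size equalization.

Classification (`classify_stability`) then applies three filters: mean
FPKM or mean DPKM ≥ 1 (abundance), BH-adjusted FDR < 0.01 (significance),
and |log₂ FPKM/DPKM| > 2.5 (effect size). Positive log-ratios (RNA-seq
excess) are **stable**; negative are **unstable**. A 0.5 pseudo-count
enters the fold change only when exactly one pooled count is zero.

## 4. Endonucleolytic cleavage calling

A discrete internal cleavage produces a dominant 5′-end peak. For each
transcript and replicate the pipeline computes the **SOA** (sum of all tag
abundances, RPM) and the **Max-seq** (the most abundant position, ties
broken 5′-most), then applies a four-filter cascade
(`call_endonucleolytic`):

* F1 — identical Max-seq position in both replicates;
* F2 — SOA > 50 RPM;
* F3 — Max-seq abundance > 10 RPM;
* F4 — Max-seq / SOA ratio > 0.2.

F2–F4 use replicate means by default (`per_replicate = TRUE` requires each
replicate to pass). Thresholds are strict inequalities. Survivor counts
per filter are logged so monotonicity is checkable. Call positions are
summarized as percentile bins along the cDNA,
bin = ⌈100 · (position + 1) / length⌉, so the first base falls in bin 1
and the last in bin 100.

## 5. Cap inference and decapping

Each transcript gets a 400-nt window: 200 nt of genomic sequence upstream
of the annotated TSS plus the first 200 nt of cDNA (`build_windows`);
offset 0 is the first transcribed nucleotide. Tag libraries are projected
into these windows at up to one mismatch (`project_tags_to_window`), with
RPM computed over in-window hits.

C-PARE windows pass through a three-filter cascade (F1 same Max-seq offset
in both replicates, F2 Max-seq > 10 RPM, F3 Max-seq/total ratio > 0.2) to
yield an empirical **cap position** per transcript
(`infer_cap_position`). The PARE windows are filtered identically, and a
transcript is called **decapped** when its filtered PARE Max-seq offset
equals its inferred cap offset (`call_decapped`) — decapping exposes a 5′
monophosphate at the cap site itself. `offset_distribution` reports the
cap-offset histogram and the two headline fractions (caps exactly at
offset 0; caps within 50 nt).

## 6. Synthetic data generator

`sim_config` fixes the study conditions; the defaults define the standard
fixture used throughout the tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| `n_transcripts` | 500 | large enough for stable FDR behavior, small enough for minutes-scale runs |
| `length_range` | 500–1500 nt | covers short/long cDNAs; minimum 500 keeps windows and planted sites feasible |
| `tss_upstream_pad` | 300 nt | guarantees full 200-nt upstream window flanks |
| `frac_stable` / `frac_unstable` | 0.2 / 0.2 | large planted fractions deliberately stress the composition correction |
| `effect_log2` | 4 | planted decay factors 2^±4, comfortably beyond the 2.5 call threshold |
| `frac_cleaved` / `frac_decapped` | 0.1 / 0.1 | disjoint sets; cleaved transcripts are never planted stable |
| `peak_fraction` | 0.4 | planted peak weight; the remaining 0.6 is uniform background, giving Max-seq ratios ≈ 0.4 |
| `background_decay_tags` | 2000 | per-transcript expected tag mass; library size = n × 2000 = 10⁶ |
| `nb_dispersion` | 0.05 | typical RNA-seq overdispersion |
| `expr_sdlog` | 0.5 | lognormal expression spread |
| `cap_jitter_sd` | 0 | C-PARE starts exactly at the cap; positive values spread them with discretized-normal jitter |

The generator builds an SSR-free transcriptome (so no planted signal is
lost to the SSR filter — a deliberate simplification), places each
transcript on a random strand with ≥ 300 nt of genomic padding, and draws
each tag library as one multinomial over (transcript, position) cells, so
library totals are conserved exactly. PARE cell weights are expression ×
decay-factor, split between uniform background and planted peaks; C-PARE
weights are expression concentrated at the cap. RNA-seq counts are
negative binomial (Poisson at dispersion 0). All stages derive their RNG
seeds deterministically from the one user seed, so equal seeds give
byte-identical outputs.

Known limits: single-exon, single-isoform transcripts; uniform background
decay rather than position-dependent exonucleolytic profiles; no
sequencing errors (the 1-mismatch mapper is exercised by planted mutated
tags in the tests instead); the mitochondrial contig is random sequence.

## 7. Numerical and engineering choices

* Exact-test probabilities are computed in log space and normalized before
  exponentiation; the observed-probability comparison uses a 10⁻⁸ log
  tolerance so ties are included.
* The Hamming mapper verifies candidates with vectorized integer
  comparisons over a concatenated code array — no per-candidate loops.
* Every figure (`make_dplot`) writes a TSV twin so the numbers behind a
  plot are testable without parsing images.
* All result tables are written deterministically (stable ordering, no
  timestamps), making byte-identity a meaningful acceptance check.

## Worked example

```{r, eval = FALSE}
library(parecall)
run <- run_degradome(sim_config(seed = 1))
print(run)
evaluate_recovery(run)
write_degradome(run, "results/run_seed1")
```

`evaluate_recovery` compares every call set against the planted truth and
reports sensitivities, swap counts, false-positive rates and exact
position recovery.
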