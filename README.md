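# parecall

Analysis of RNA degradome tag libraries: transcript stability
classification, endonucleolytic cleavage detection and decapping
detection from 5′-end sequencing data, with a fully seeded synthetic
benchmark.

## The science

When an mRNA is degraded 5′→3′, cleaved internally, or decapped, the
decay intermediate carries a 5′ monophosphate. **PARE** libraries
(parallel analysis of RNA ends) sequence 20-nt tags from exactly these
5′ ends, so in an XRN1-depleted background — where 5′-monophosphate
intermediates accumulate instead of being chewed back — tag positions and
abundances read out *where and how much* decay happens on every
transcript. A companion **C-PARE** library profiles the 5′ ends of capped
transcripts and locates each transcript's empirical cap.

From these two tag types plus matched RNA-seq, `parecall` computes:

* **Stability classes.** A transcript whose steady-state abundance (FPKM,
  from RNA-seq) far exceeds its decay-product abundance (DPKM, from PARE
  tags) is *stable*; the reverse is *unstable*. Both use the same
  normalization, count × 10⁹ / (length × library total), so their ratio is
  a unitless relative decay rate. Significance comes from an exact
  conditional count test: replicate counts are scaled to the geometric
  mean of the (composition-corrected) library sizes and pooled, and,
  conditional on the pooled total *t*, the RNA-seq count is
  binomial(*t*, ½) under the null (dispersion 0) or negative
  hypergeometric (common NB dispersion > 0). Calls require
  Benjamini–Hochberg FDR < 0.01, |log₂ FPKM/DPKM| > 2.5, and mean FPKM or
  DPKM ≥ 1.
* **Endonucleolytic cleavage sites.** A discrete internal cut concentrates
  tags at one position. The four-filter cascade keeps transcripts whose
  most abundant tag position (**Max-seq**) is replicate-reproducible (F1),
  whose total tag abundance (**SOA**) exceeds 50 RPM (F2), whose Max-seq
  exceeds 10 RPM (F3), and whose Max-seq/SOA ratio exceeds 0.2 (F4).
* **Cap positions and decapping.** Tags are projected into ±200-nt windows
  around each annotated TSS. The C-PARE Max-seq offset, filtered by a
  three-filter cascade, is the empirical cap; a transcript is *decapped*
  when its filtered PARE Max-seq falls exactly at that cap offset —
  decapping exposes a monophosphate at the cap site itself.

Every analysis runs on synthetic experiments with planted ground truth
(`sim_config` → `simulate_degradome`), so sensitivities and
false-positive rates are measurable, not asserted. See
`vignettes/degradome-methods.Rmd` for the complete model and parameter
rationale.

## Worked example

```r
library(parecall)

# Simulate the standard fixture and run the full pipeline
run <- run_degradome(sim_config(seed = 1))
print(run)
#> Degradome pipeline run
#>   transcripts:        500
#>   stable / unstable:  100 / 100
#>   cleavage calls:     89
#>   cap positions:      500
#>   decapped calls:     50

# Compare every call set against the planted truth
str(evaluate_recovery(run))
#> List of 9
#>  $ sensitivity_stable    : num 1
#>  $ sensitivity_unstable  : num 1
#>  $ class_swaps           : int 0
#>  $ null_nonneither_rate  : num 0
#>  $ cleavage_recall       : num 1
#>  $ cleavage_exact        : num 1
#>  $ cleavage_fpr          : num 0
#>  $ decap_recall          : num 1
#>  $ decap_fp_cleavage_only: num 0

# 89 cleavage calls = 50 planted cleavage sites + decap peaks that are
# themselves dominant 5'-end signals; none fall on unplanted transcripts.

# Deterministic result tables + JSON summary
write_degradome(run, "results/run_seed1")
```

Lower-level entry points mirror the pipeline stages: `trim_reads` →
`filter_tags` → `map_tags` (preprocessing), `abundance_table` →
`stability_test` → `classify_stability` (stability),
`call_endonucleolytic` (cleavage), `build_windows` →
`project_tags_to_window` → `infer_cap_position` → `call_decapped`
(capping), and `build_decay_profile` / `make_dplot` /
`replicate_correlation` / `summary_tables` (reporting). A thin CLI lives
at `inst/scripts/parecall-cli.R`.

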