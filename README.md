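# ctdnaflow

Somatic variant filtering and longitudinal response tracking for
targeted-panel circulating tumor DNA (ctDNA) sequencing.

Deep sequencing of plasma cell-free DNA (cfDNA) with a small cancer gene
panel can detect tumor mutations non-invasively and repeatedly during
therapy — but at 1% allele fractions the raw call set is dominated by
germline polymorphisms, clonal hematopoiesis (CH) and sequencing noise.
`ctdnaflow` is for analysts of serially sampled treatment cohorts
(plasma + matched PBMC + archival tumor tissue) who need a tested,
reproducible path from per-sample variant calls to clinical endpoints.

## What it implements

**The filter cascade.** With deduplicated depth *d*, variant reads *a*
and VAF = *a*/*d*, per sample:

- panel gate, then functional-class selection (missense, stop-gain,
  stop-loss, in-frame deletion, frameshift);
- material thresholds, boundaries inclusive —
  cfDNA: VAF ≥ 1% and *a* ≥ 10; tissue: VAF ≥ 10% and *a* ≥ 10;
- germline subtraction: PBMC calls at VAF ≥ 20% (het ≈ 50%, hom ≈ 100%)
  removed patient-wide;
- CH/noise blacklist: PBMC calls < 20% VAF pooled over *all* PBMC
  samples, removed cohort-wide;

with a complete per-call disposition log, and UMI-based duplicate
collapsing (strict-majority family consensus, ties dropped) when read
records are the input.

**Longitudinal endpoints.** Per patient and timepoint, the average VAF
(unweighted mean over detected somatic mutations, percent; 0 when none);
clearance at the first evaluation (average VAF < 1%, strict); tissue ↔
plasma concordance with sub-threshold rescue of filtered signal;
emergent (resistance-candidate) mutations at progression, i.e. PD-only
variants absent from all earlier plasma and tissue somatic sets, with
hotspot and pathogenicity annotation from bundled catalogues.

**Cohort statistics.** Kaplan–Meier/log-rank PFS comparisons,
Pearson/Spearman correlations, Mann–Whitney (exact for small samples),
chi-square/Fisher 2×2 association with automatic test choice, per-gene
frequency tables, and the exact two-sided binomial power computation for
enrollment design.

**A synthetic cohort generator** (`simulate_cohort()`) that emits the
exact input formats with full ground truth — germline/CH/somatic/
emergent roles, clearance labels, PFS — so every stage is verifiable
end to end without patient data.

## Worked example

```r
library(ctdnaflow)

cohort <- simulate_cohort(sim_params(n_patients = 93, seed = 7))
report <- analyze_cohort(cohort$calls, cohort$samples, cohort$clinical)
report
#> <ctdna_report> 93 patients; 86 (92.5%) mutation-positive at baseline;
#> 228 baseline mutations; 56 emergent at PD

head(report$frequency_baseline$table, 3)
#>   gene  n_mutations n_patients panel_restricted pct_patients
#> 1 APC           115         69 FALSE                    74.2
#> 2 TP53           62         46 FALSE                    49.5
#> 3 ERBB2          16         16 FALSE                    17.2

report$survival_by_clearance[c("median_pfs", "logrank_p")]
#> $median_pfs$cleared      12.174
#> $median_pfs$not_cleared   7.083
#> $logrank_p            0.0466

corr <- report$correlations$baseline_vaf_vs_size
#> baseline average VAF vs tumor size: r = 0.599 (p = 2.2e-10, n = 93)

head(report$emergent[, c("patient_id", "gene", "aa_change", "vaf",
                         "hotspot", "pathogenicity")], 4)
#>   patient_id gene  aa_change     vaf hotspot  pathogenicity
#> 1 P009       APC   <NA>       0.0950 none     none
#> 2 P010       APC   <NA>       0.108  none     none
#> 3 P010       ERBB2 <NA>       0.0514 none     none
#> 4 P015       KRAS  p.Gly12Val 0.0515 KRAS_G12 pathogenic
```

Reading: 92.5% of the simulated patients have detectable ctDNA at
baseline with APC and TP53 leading the gene frequency table; patients
whose average VAF cleared below 1% at the first evaluation progress
later (median PFS 12.2 vs 7.1 months, log-rank p = 0.047); baseline
ctDNA burden correlates with radiographic tumor size (r ≈ 0.6); and at
progression, new RAS-pathway mutations (here KRAS p.Gly12Val, a known
anti-EGFR resistance hotspot) emerge in plasma.

The same analysis runs from files: `write_cohort(cohort, dir)` then
`run_pipeline(run_config(dir, out_dir = "out"))`, which writes TSV/JSON
artifacts with a manifest. All thresholds live in
`filter_config()`/`run_config()` with the defaults above, so the
canonical analysis is the zero-argument invocation.

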