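---
title: "Somatic filtering and longitudinal tracking of ctDNA panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic filtering and longitudinal tracking of ctDNA panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaflow)
```

## The problem

Plasma cell-free DNA (cfDNA) of a cancer patient contains a minor
tumor-derived fraction (ctDNA). Deep targeted sequencing of a small gene
panel can detect tumor mutations in plasma non-invasively, repeatedly, and
— because blood pools DNA shed from all lesions — with less exposure to
spatial tumor heterogeneity than a single biopsy. The analytical problem
is separating true tumor signal from three contaminants that dominate at
the relevant allele fractions: germline polymorphisms (heterozygous near
50% VAF, homozygous near 100%), clonal hematopoiesis (CH; blood-derived
somatic variants at low VAF present in both plasma and white cells), and
sequencing/PCR noise.

`ctdnaflow` implements a complete small-panel ctDNA workflow for a
serially sampled treatment cohort: molecular-barcode deduplication, a
material-aware filter cascade with matched-PBMC germline subtraction and
a cohort-level CH/noise blacklist, per-patient average-VAF trajectories
with a clearance classifier, tissue–plasma concordance with
sub-threshold rescue, emergent-mutation detection at progression, and
the cohort statistics (Kaplan–Meier/log-rank, correlations, rank tests,
frequency tables, exact binomial power). A synthetic cohort generator
with full ground truth makes every stage testable without patient data.

## The filter cascade

Each sequenced sample is a list of variant calls with deduplicated depth
$d$, variant-supporting reads $a$, and VAF $= a/d$. The cascade applies,
in canonical order:

1. **Panel gate.** Calls in genes outside the sample's panel version
   (11-gene v2 or its 16-gene superset v3) are excluded from all counts.
2. **Functional class.** Only missense, stop-gain, stop-loss, in-frame
   deletion and frameshift calls are retained ("possibly functional"
   classes); synonymous and other annotations are dropped.
3. **Material thresholds** (inclusive boundaries):
   - cfDNA: keep iff VAF $\ge$ 1% **and** $a \ge 10$. The permissive VAF
     cutoff reflects the small ctDNA fraction of plasma cfDNA.
   - tissue: keep iff VAF $\ge$ 10% **and** $a \ge 10$.
   - PBMC samples never pass through this filter; they take the
     germline/blacklist path below.
4. **Germline subtraction (patient scope).** PBMC calls at VAF $\ge$ 20%
   are declared germline and removed from the same patient's cfDNA and
   tissue results.
5. **Blacklist subtraction (cohort scope).** PBMC calls **below** 20%
   VAF, pooled over every PBMC sample in the cohort, form a blacklist of
   recurrent noise and CH variants removed from all samples of all
   patients.

Every input call receives exactly one disposition
(`kept`, `dropped:panel`, `dropped:class`, `dropped:threshold`,
`dropped:germline`, `dropped:blacklist`, `dropped:manual`), germline
being logged before blacklist when both match. Re-running the cascade on
its own kept output is a no-op.

Three boundary decisions were genuinely open and are resolved as
follows:

- **The 20% boundary.** "More than 20%" (germline) and "less than 20%"
  (blacklist) leave VAF = 20% unassigned; we assign the boundary to
  germline (`vaf >= 0.20`), so the two PBMC branches partition every
  PBMC call with a single comparator.
- **Blacklist recurrence.** Whether the blacklist required a variant in
  two or more PBMC samples is unstated; the default admits singletons
  (conservative: more removal), with `min_recurrence` exposed for
  sensitivity analysis.
- **Visual inspection.** Pileup review in a genome browser is not
  automatable; it is represented by an optional manual-exclusion key
  list (`dropped:manual`) so that a curated analysis remains
  reproducible.

Floating-point guard: percent thresholds are converted to fractions once,
and all `>=`/`<` comparisons carry an epsilon of $10^{-12}$ so that calls
lying exactly on a boundary are classified by the rule, not by the
rounding of `x/100`.

## Barcode deduplication

For cfDNA libraries a random barcode (UMI) identifies the founding
molecule of each read. Reads are grouped by the exact tuple
(UMI, chromosome, start, strand); each family contributes one consensus
observation, the strict majority allele of its members, and tied
families are dropped from both depth and variant counts. Two decisions
are package choices, not claims about the original laboratory pipeline,
which does not document them: exact-match UMI grouping (no
edit-distance merging — deterministic and collision-safe at panel scale)
and strict-majority-with-tie-drop consensus (a conservative reading of
"discard sequencing errors"). Deduplication is idempotent, never
increases depth, and with no duplicates and no errors reproduces the raw
VAF exactly. When inputs arrive as variant tables or VCFs, counts are
taken to be already deduplicated; the package treats post-deduplication
counts as the canonical VAF denominator.

## Longitudinal tracking

The per-sample burden summary is the **average VAF**: the unweighted
mean VAF (percent) over all somatic mutations detected at that
timepoint, 0 when none is detected. The denominator is
detection-based — not a fixed baseline-tracked set — for two reasons:
under combined cytotoxic and targeted therapy the dominant clone can
change, and a tracked-set convention could never fall to the "nothing
detectable" state that the clearance rule below requires.

**Clearance** at the first response evaluation is strict:
average VAF $< 1\%$ is `cleared`, exactly 1% is `not_cleared`, and a
missing first-evaluation sample yields `unknown` (excluded from survival
comparisons).

**Concordance** matches tissue somatic variants against the baseline
cfDNA somatic set by exact variant key (a positional mode exists for
indel-representation drift). An unmatched tissue variant found in the
post-class, pre-threshold cfDNA calls with VAF $> 0$ is
"rescued sub-threshold": real tumor signal sacrificed to the restrictive
1% filter rather than absent from plasma. The symmetric check flags
ctDNA-only variants present sub-threshold in unfiltered tissue.

**Emergent mutations** at progression are PD-set variants absent from
*all* earlier cfDNA somatic sets and from the tissue somatic set.
Screening against every earlier timepoint (not baseline only) was an
open reading; the stricter screen was chosen because a variant present
at any interim evaluation already existed before resistance emerged.

## Cohort statistics

Standard machinery is delegated to the standard implementations
(`survival::survfit`/`survdiff`, `cor.test`, `wilcox.test`,
`chisq.test`/`fisher.test`), wrapped behind a uniform interface:
two-sided tests throughout, no multiplicity correction (raw p-values are
reported, as is conventional for exploratory biomarker cohorts),
Mann–Whitney exact for combined $n \le 16$ without ties, and the 2×2
association test chooses Fisher's exact test when any expected cell is
below 5 (the choice actually applied is always reported, and both
p-values are available). The test suite verifies each wrapper against an
independent oracle: hand product-limit arithmetic, a hypergeometric
log-rank sum, full-permutation Mann–Whitney enumeration, and rank-based
Spearman equivalence.

The enrollment power computation is authored in-package: the exact
two-sided binomial test's rejection region is enumerated by the
minimum-likelihood rule and the alternative mass summed over it. Exact
power is *not* strictly monotone in $n$ — between jumps of the critical
value it declines slightly (dips up to ~0.035 on the grid
$n \in [10, 100]$ at $p_0 = 0.7$, $p_1 = 0.9$) — so the tests assert the
true property: a nondecreasing upper envelope with bounded dips. At a
40% prevalence of informative alterations, the evaluable size for a
93-patient enrollment is `n_evaluable(78, 0.4) = 31`, where the exact
power of detecting a sensitivity improvement from 0.7 to 0.9 at
$\alpha = 0.05$ is 80.7%.

## The synthetic cohort generator

`simulate_cohort()` emits, per patient, PBMC, baseline cfDNA and
first-evaluation cfDNA samples (plus archival tissue and PD cfDNA where
available), together with a complete truth file. Its defaults *are* the
study conditions the pipeline was designed for, fixed once:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 93 | enrolled cohort size |
| `depth_mean` | 2000× | targeted-panel deduplicated depth |
| `dropout_rate` | 0.097 | fraction with no detectable ctDNA |
| `somatic_mean` | 2.74 | mutations per mutation-positive patient |
| `burden_meanlog` | −1.74 | log-normal (sdlog 1, truncated to 3–90%) calibrated numerically so the cohort mean of per-patient average VAF is ≈ 23.3% |
| `germline_het`/`hom` | 12 / 4 | panel-scale germline variant counts, VAF ~ N(0.50, 0.02) / 0.985–1.0 |
| `ch_pool_size`, `ch_vaf_range` | 15, 1–12% | shared CH variants below the 20% boundary |
| `shedding_coef`, `size_noise_sd` | 1 mm per VAF point, 22 mm | burden–size coupling; gives Pearson r centred near 0.6 at n = 200 |
| `response_probs` | PR/SD/PD = 0.750/0.207/0.043 | observed response mix |
| `clearance_by_response` | 0.88/0.48/0.10 | marginal clearance rate ≈ 76.2% |
| `tissue_rate`, `pd_sample_rate` | 0.71, 0.58 | availability of tissue / PD blood |
| `hr_clearance`, `median_pfs_cleared` | 2.16, 11.9 mo | exponential PFS; implied not-cleared median ≈ 5.5 mo |

Read counts are binomial draws at per-locus depth ~ N(2000, 200). Every
patient is generated from a substream derived deterministically from the
run seed and the patient index, so patient *i* is reproducible
independent of cohort size, and a fixed seed reproduces the emitted
files byte for byte.

**Guard bands.** Planted truth keeps a deliberate margin from every
decision boundary: detectable somatic VAF ≥ 3%, cleared patients' true
first-evaluation mean ≤ 0.33%, not-cleared ≥ 2.7%, emergent VAF ≥ 3%,
CH ≤ 12%, germline heterozygotes ≥ 35%. At 2000× depth the binomial
read noise is then at least ~4 standard deviations away from flipping
any planted label across the 1% detection/clearance cutoff, the 10%
tissue cutoff or the 20% germline boundary, which is what makes the
"recovered exactly" tests meaningful rather than flaky. Sub-threshold
shedding (tissue variants at 0.1–0.3% cfDNA VAF) and synonymous calls
are planted to exercise the rescue logic and the class filter.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: position-specific error spectra and
context-dependent artifacts (noise is pure binomial), indel
representation ambiguity, CH VAF drift over time (CH is static), clonal
evolution between timepoints other than the bimodal
clearance/progression pattern, panel drop-out regions, and
contamination. In particular, the change in average VAF between baseline
and first evaluation is essentially bimodal by construction, so its
correlation with radiographic size change is weak in simulation even
though the clearance–response coupling is present; the corresponding
patient-level correlation and survival figures of a real cohort are not
reproducible from synthetic data and are not targeted.

## Problem sizes used in the checks

Exactness and recovery properties are verified on a 200-patient cohort
(one seed, full pipeline), generator shape properties on a 500-patient
run, the burden–size correlation on 20 independent 200-patient seeds,
and log-rank power at hazard ratio 3 on 200 replicates of 40 + 40
patients — sizes at which every Monte-Carlo band in the suite has
comfortable margin.

## Known limitations

- Concordance matching is key-exact by default; left-alignment of indels
  is assumed on input rather than re-normalized against a reference.
- The blacklist models CH as cohort-static; a per-timepoint PBMC design
  would allow treatment-emergent CH to be separated from tumor signal.
- The pipeline accepts the clinical table's per-timepoint lesion size as
  an opaque scalar (largest-lesion diameter or RECIST sum, whichever the
  table provides) and does not adjudicate between the two conventions.
- No multiple-testing correction is applied anywhere; consumers
  performing many gene-level comparisons should correct downstream.
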