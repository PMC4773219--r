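---
title: "Rare CNV discovery in case-control cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV discovery in case-control cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

# The problem

Hypertension-related left ventricular hypertrophy (LVH) is a complex,
polygenic condition; under a rare-variant model, part of its heritability
is expected to come from copy number variants (CNVs) that are individually
rare — population-specific, or even private to single patients. Detecting
such variants from SNP-array data is dominated by false-positive control:
single-algorithm CNV calls from array intensities have high error rates,
and most detected CNVs are common polymorphisms irrelevant to a rare-variant
hypothesis.

`rarecnv` implements the complete discovery pipeline for this setting:
phenotype classification, per-sample array quality control, multi-algorithm
consensus calling, CNV-level filtering, rarity/novelty assessment against
reference catalogues, case/control specificity, recurrence detection and
burden statistics — together with a synthetic-data generator that emulates
the whole study design with a ground-truth ledger, so that every stage can
be tested for exact recovery.

# Phenotype model

Left ventricular mass is estimated from M-mode echocardiography by the
Devereux-corrected cube formula,

$$\mathrm{LVM} = 0.8 \cdot \{1.04\,[(\mathrm{LVIDD} + \mathrm{PWTD} +
\mathrm{IVSTD})^3 - \mathrm{LVIDD}^3]\} + 0.6\ \mathrm{g},$$

with the internal dimension (LVIDD) and wall thicknesses (PWTD, IVSTD) in
cm. The mass index is LVMI = LVM / height² (g/m²), and LVH is diagnosed
when LVMI *strictly exceeds* 110 g/m² in women or 125 g/m² in men. The
additive 0.6 g correction follows the standard Devereux reading; both the
correction and the thresholds are parameters (`lvh_thresholds()`), so a
multiplicative variant could be swapped in if a cohort's convention
differed. Boundary semantics matter for classification: an LVMI of exactly
110 g/m² in a woman is *not* LVH.

Cohort summaries use Welch's two-sample t-test for continuous variables and
a chi-square test (Fisher's exact fallback when any expected cell count is
below 5) for sex composition. The source study reports P-values without
naming its tests; Welch is the default because group variances cannot be
assumed equal.

# Sample quality control

A sample is excluded when any of the following holds (strict inequalities;
a metric exactly at its bound passes):

| metric            | rule      | default | meaning |
|-------------------|-----------|---------|---------|
| call rate         | `< 0.99`  | 0.99    | fraction of probes with a genotype call |
| LRR SD            | `> 0.35`  | 0.35    | noise of the log R ratio (total intensity) |
| BAF SD            | `> 0.13`  | 0.13    | spread of the heterozygous B-allele-frequency band |
| batch ratio SD    | `> 0.27`  | 0.27    | per-probe intensity ratio to the batch median profile |

Two estimators require definitions the thresholds alone do not supply:

* **BAF SD** is computed over probes in the heterozygous band
  [0.25, 0.75] only. The full-range BAF SD is dominated by the homozygous
  clusters at 0 and 1 and would sit near 0.45 for every sample, making a
  0.13 threshold meaningless.
* **Batch-normalized ratio SD** has no published formula; it is
  implemented here as the SD of each sample's per-probe intensity ratio to
  the per-probe batch median profile, with intensity derived as
  `2^LRR` when raw ratios are not supplied. This is a surrogate definition,
  configurable at `compute_qc_metrics()`.

After consensus calling, samples that are upper outliers in **aggregate CNV
length** are additionally excluded. "Outlier" is fixed to the Tukey upper
fence Q3 + 3·IQR (type-7 quartiles) over kept samples: robust,
deterministic and parameter-light. With fewer than four samples no fence is
estimable and the test is skipped with a warning; a sample with no calls
has aggregate length zero and can never be an upper outlier.

# Consensus calling and CNV filters

Each sample is called by three independent algorithms. A *stringent* call
is one supported by at least two of them. Because the source procedure
never defines "the same call", merging is explicit here: within
(sample, chromosome, CNV type), two calls are linked when they overlap
**reciprocally at ≥ 50%** — the intersection covers at least half of *each*
call — and clusters are the single-linkage closure of those links. The
consensus interval spans the cluster's outer bounds; supporting algorithms
are the distinct labels in the cluster. Outer bounds are the conservative
choice for the downstream overlap rules, and both the linkage fraction and
the boundary rule (outer / inner / median) are configurable in
`merge_algorithm_calls()`. Single-linkage means a chain A~B~C merges even
when A and C do not overlap; the suite verifies the clustering against an
exhaustive pairwise-closure oracle on small instances.

Consensus calls then pass five filters (`apply_cnv_filters()`), each with
an exact boundary convention:

| filter      | excluded when            | boundary |
|-------------|--------------------------|----------|
| FEW_PROBES  | `probe_count < 5`        | 5 probes pass |
| HIGH_GC     | mean GC `> 0.70`         | 0.70 passes |
| CENTROTELO  | gap to centromere/telomere `< 30 kb` | 30,000 bp passes |
| TOO_SMALL   | length `< 1 kb`          | 1,000 bp passes |
| SEX_CHROM   | chrX or chrY             | — |

GC content is the length-weighted mean of the overlapped windows of a
fixed-width GC track, which matches windowed annotation tracks without
requiring raw sequence. The "approximately 30 kb" proximity rule is a
strict gap threshold. Calls longer than 1 Mb — which the original
procedure removed by manual visual inspection, something automation cannot
reproduce — get a `LARGE_CALL` review flag but are *not* auto-excluded; an
optional hard cap (`large_call_cap`) is available. Every filter outcome
carries its full reason set, and the tally conserves: input = retained +
excluded, with multi-reason calls counted once in the total.

# Rarity, specificity, recurrence

A filtered call is assessed by three rules, applied in a fixed order so the
stage tallies are auditable (the source lists the rules unordered):

1. **Known CNP** — the call overlaps, by at least one base, a reference
   variant with population frequency > 1%. Frequency must strictly exceed
   the threshold; an overlap with a 0.5%-frequency variant does not
   trigger the rule.
2. **Known in references** — some variant in any reference catalogue
   (DGV-like, HapMap3-like, SGVP-like, checked sequentially with per-set
   match records) overlaps the call reciprocally at ≥ 50%. The source
   phrases the keep-side as "< 50%" and the exclude-side as "> 50%",
   leaving exactly 50% contradictory; it is implemented as *excluded*
   (≥ 0.5) and parameterized.
3. **Singleton status** — calls of the same type are linked across samples
   at ≥ 50% reciprocal overlap (single linkage); a call in a cluster
   spanning two or more distinct samples is a non-singleton.

Case/control specificity is then computed on the calls surviving rules 1
and 2: a case call is case-specific iff no control call of the same type
links to it at the linkage fraction (and symmetrically). This set —
not the singleton-only subset — feeds recurrence detection, because the
design explicitly reports recurrent case-specific loci carried by two or
three cases, which a strict singleton cut would erase. Singleton status is
carried per call for reporting. Specificity is tested against *all*
surviving control calls (not only rare ones), the conservative choice; the
linkage fraction is shared with the merge step for internal consistency
and configurable throughout.

Recurrent loci are occurrence clusters among case-specific calls with at
least 2 distinct carriers, reported with outer-bound coordinates and the
genes they disrupt. Gene disruption means any ≥ 1 bp intersection with a
gene model (a containment-only mode exists); calls touching no gene render
as a dash.

The burden report gives per-group totals with gain/loss splits, per-genome
means (total / genomes; the conventional two-decimal rendering of these
averages truncates), length mean/median, a size-bin percentage histogram
over decade bins 1 kb–1 Mb, and a Welch t-test on call lengths (rank-based
alternative available).

# The synthetic study

`simulate_study()` generates every input the pipeline consumes, under a
single seed, with a ground-truth ledger:

* **Genome scaffold** — by default three autosomes plus chrX
  (60/50/40/30 Mb), telomeres at both ends, a 1 Mb centromere mid-arm, a
  10 kb-windowed GC track with 2% of windows pushed above 0.70 (so the GC
  filter is exercised), and probes every 5 kb (~36,000 probes). This is a
  deliberate desk-scale stand-in for a ~660k-probe genome-wide array; full
  scale is a config change.
* **Cohort** — 44 cases and 72 controls (116 genomes), sexes drawn at the
  study's observed male fractions, and echo measurements *solved backwards*
  through the Devereux formula from target LVMI values placed above
  (cases) or below (controls) the sex-specific threshold, so the phenotype
  module closes the loop exactly; a configurable error rate plants
  misclassifications.
* **CNV landscape** — four locus classes: common polymorphisms (default 12
  loci, frequencies 5–30%, carriers by per-sample binomial draws), shared
  rare loci (carried by at least one case and one control), singletons
  (Poisson, mean 2 per genome), and recurrent case loci (3 loci carried by
  3, 2 and 2 cases, mirroring the reported recurrence pattern). Loci are
  30–100 kb (log-uniform), 80% losses, placed to pass every CNV filter
  with margin and separated by ≥ 200 kb so no two distinct loci ever link
  at 50% reciprocal overlap.
* **Reference catalogues** — every planted polymorphism appears in the
  DGV-like set at its true frequency (subsets in the HapMap3-/SGVP-like
  sets), plus decoy variants placed away from all planted loci.
* **Callers** — three algorithms, each emitting each true CNV with
  sensitivity 0.95, breakpoint jitter uniform within ±10% of locus length
  per side, and Poisson false positives (2 per genome) placed at least
  50 kb from every planted locus so ledger provenance is unambiguous.
  The emulation is call-level by design: the upstream callers'
  intensity-space HMMs are out of scope, and calls are what the pipeline
  consumes. LRR/BAF/genotype matrices are generated only to exercise the
  QC estimators (2,000 probes by default), with optional injected
  failures per QC metric.

## What the simulation does and does not show

The generator reproduces the *combinatorial* structure of the study —
locus sharing, consensus support, reference membership, group labels — and
the closed loop is exact: with perfect sensitivity and no jitter or false
positives, the pipeline's final case-specific set equals the ledger's
planted case-only loci exactly, and no planted polymorphism survives the
rarity stage. Under the realistic noise defaults, ≥ 90% of planted rare
case loci are recovered with ≥ 95% precision.

It does not emulate intensity-level artifacts (GC waves, batch structure
correlated across probes), LD between loci, breakpoint hotspots, or
reference catalogues whose coordinates disagree with the sample's calls by
more than breakpoint jitter. Passing the closed loop therefore validates
the pipeline's logic and bookkeeping, not the error characteristics of any
particular calling algorithm on real arrays.

One interaction deserves note: the aggregate-length outlier fence can
legitimately exclude a sample whose (Poisson) singleton load is heavy, and
that sample's planted loci are then unobservable downstream. Recovery is
therefore always measured against the ledger restricted to analyzed
genomes (`ledger_case_specific()`), which also accounts for a shared locus
becoming case-specific when its control carriers were excluded. This
mirrors real studies, where specificity is defined relative to the cohort
that survived QC.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; 1-based closed
  conventions (PennCNV-style `rawcnv`, DGV-style reference TSVs) are
  converted at the I/O boundary, making the conversion an involution.
  Lengths are always `end − start`.
* All threshold comparisons use the exact arithmetic stated above; the
  suite checks each boundary at one ulp.
* Cluster ids are renumbered by first appearance in (key, start) order, so
  outputs are deterministic and byte-identical across reruns; every report
  writer sorts explicitly (chromosome in karyotype order, then start, then
  sample).
* Degenerate inputs: empty call files yield empty call sets; a chromosome
  absent from the probe manifest yields probe_count 0 with a warning; a
  missing GC track skips the GC filter with a prominent warning; a
  single-group cohort yields a summary without comparison statistics;
  zero-variance groups yield statistic 0 and p = 1 rather than NaN.
* Duplicate (algorithm, sample, interval) calls collapse with a warning
  before merging, so replicated input files cannot inflate support counts.

# Problem sizes

The default simulated study is 116 genomes over a 180 Mb genome with
~36,000 probes and ~280 planted loci (~2,300 emitted calls); a full
pipeline run takes a few seconds. The test suite runs the clustering
oracles on hundreds of small random instances and two full-cohort
simulations. These sizes were chosen so the whole analysis re-runs in
about a minute while every planted locus class and filter is exercised;
they are configuration, not limits.

# Known limitations

* The batch-ratio QC metric is a surrogate definition (see above).
* Merge semantics (linkage fraction, boundary rule) are a documented
  choice, not a reconstruction of any specific caller-merging tool;
  sensitivity to the boundary rule is untested beyond idempotence.
* Gene annotation is symbol-level interval intersection; no
  transcript-aware disruption model.
* No GC-wave correction, intensity re-segmentation, or breakpoint
  refinement beyond member-call bounds.
* Ontology/pathway enrichment and wet-lab validation of candidate loci are
  out of scope.
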