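---
title: "Rare CNV burden association: models, quality control and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV burden association: models, quality control and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
library(data.table)
```

## The analysis problem

Rare copy-number variants (CNVs) — deletions and duplications larger than
about 10 kb at below 1% population frequency — are established risk factors
for neurodevelopmental and psychiatric phenotypes. Testing whether they
carry risk for a quantitative symptom phenotype collected across many
heterogeneous cohorts requires a long chain of processing, and each link has
conventions that matter for the result:

1. **Consensus calling.** CNV calls from SNP-array intensity data are
   noisy, so calls from two independent algorithms are intersected; only
   loci where both callers agree on dosage direction survive. Calls labelled
   gain by one caller and loss by the other at the same locus (more than 50%
   reciprocal overlap) are contradictory and both are discarded.
   Large CNVs are often emitted as several fragments; adjacent same-type
   calls are *annealed* when the gap between them is less than 30% of the
   overall annealed length, iterated to a fixed point.
2. **Quality control.** Samples are dropped when array-quality metrics
   (log-R-ratio SD, B-allele-frequency SD, waviness), CNV count or kb burden
   reach Q3 + 3·IQR within their cohort; when more than 20% of any
   chromosome is copy-number variant (aneuploidy); or when standard
   genotype QC failed. CNVs are dropped when covered ≥50% by
   centromere/telomere/Ig/TCR loci, >50% by segmental duplications, when
   their within-data frequency exceeds 1%, or when shorter than 10 kb or
   supported by fewer than 10 probes.
3. **Burden encoding.** Four scales: genome-wide span in Mb (total, per
   type, and split by overlap with neurodevelopmental-disorder (NDD) CNV
   regions); per-region carrier status (region covered >0%, ≥50% or 100% by
   the subject's same-type calls); per-gene 0/1 indicators (≥1 bp overlap
   with the isoform-collapsed span of protein-coding genes); and gene-set
   counts (number of member genes hit).
4. **Association.** Within each cohort, the phenotype — a symptom score
   rescaled to [0, 1] by the instrument's *theoretical* range, or
   case/control status — is regressed on one burden term plus five genotype
   principal components and the log-R-ratio SD. Gene-set models add
   genome-wide CNV count and mean CNV length as covariates, so a set
   coefficient measures enrichment beyond global burden. Cohort estimates
   are combined by fixed-effects inverse-variance-weighted (IVW)
   meta-analysis, and Benjamini–Hochberg FDR is controlled within each test
   family (genome-wide spans; NDD regions per overlap rule; genes;
   gene-sets).

Individual-level data for such consortia are access-protected, so the
package ships a synthetic-data generator that emulates every input with
known ground truth, and the whole pipeline is validated against planted
values.

## Coordinate and numerical conventions

* All interval arithmetic is 0-based half-open. PennCNV-style call tables
  (1-based inclusive) are converted on read and write; BED tracks pass
  through unchanged. This removes every off-by-one ambiguity from overlap
  mathematics: intervals `[a,b)` and `[c,d)` overlap iff `a < d && c < b`.
* Quantiles for the Q3 + 3·IQR rules use linear interpolation between order
  statistics (R's default type 7); the rule must be pinned for
  bit-reproducibility. The comparison is `>=`, so a degenerate within-cohort
  distribution (IQR = 0) fails every sample sitting at Q3 — a documented
  edge case rather than a silent pass.
* Probe counts for derived intervals (intersections, annealed spans) are
  recounted from the probe map; caller-reported counts are undefined for
  intervals the caller never emitted.
* The `eq100` (complete-coverage) carrier rule is applied with a 1 bp
  tolerance, absorbing coordinate-dialect edge effects.
* Conflict exclusion requires *more than* 50% reciprocal overlap (bare 1 bp
  contact between a gain and a loss is not evidence of a contradictory
  locus); frequency clustering uses *at least* 50% reciprocal overlap, the
  standard CNV-equivalence criterion.
* Annealing is applied after intersection, greedily left to right and
  iterated to a fixed point; the 30% rule itself suppresses merging of
  distant calls, making the result order-deterministic.
* A CNV counts toward the NDD span partition when it overlaps any NDD
  region of matching type by ≥1 bp; a call is never split between the NDD
  and non-NDD partitions, so the partition sums exactly to the per-type
  total.

## The synthetic study and its planted effects

`synth_config()` fixes the study conditions; `synth_study()` generates a
complete bundle (annotation, true CNVs, two caller callsets, sample
metrics, covariates, phenotypes). Defaults:

* **Genome:** three chromosomes (60, 45, 30 Mb) with a 5 kb probe grid;
  telomeres, centromeres and one Ig/TCR-style locus; a random
  segmental-duplication track covering 2% of the genome.
* **NDD regions:** three deletion and three duplication regions between
  0.4 and 2.5 Mb — the size mix of real neurodevelopmental regions, which
  range from a few hundred kb to several Mb. Two protein-coding genes sit
  inside each region, and one gene-set (`neuro_ndd`) collects them.
* **CNV rates:** each region is carried (an event spanning the region with
  10–60 kb random extensions) with probability 0.005 per subject,
  comparable to the most frequent pathogenic microdeletions and safely
  below the 1% within-data frequency filter. Background CNVs arrive at 0.8
  per subject with log-uniform lengths 50 kb–1 Mb. Events of one subject on
  one chromosome are kept ≥2 Mb apart, which makes the zero-noise
  round-trip exact: the 30% rule can then never anneal two distinct true
  events, and opposite-type true events can never reach the conflict
  threshold.
* **Caller error:** boundary jitter SD 5 kb, fragmentation probability 0.05
  (two sub-calls with a gap below 30% of the true span, so single-caller
  fragmentation is always recoverable by annealing), false calls at 0.10
  per sample (uniform over the non-centromeric genome, log-uniform
  10 kb–1 Mb), and a 1% gain/loss flip rate. Error records may be given per
  caller. No error structure is published for real callers; these are
  modelling choices, not estimates.
* **Phenotype:** latent score `0.4 + 0.03·(NDD deletion span, Mb) +
  Σ 0.005·PC + 0.01·PRS + N(0, 0.12)` truncated to [0, 1]. Score cohorts
  map the latent value onto an instrument-specific theoretical range
  (e.g. 17–85) and emit integer raw scores, keeping the 0–1 rescaling
  invertible; one cohort is dichotomised at 0.55 into case/control. The
  intercept and noise keep truncation negligible (≈3 SD from both bounds),
  so null calibration is clean.
* **Seeding:** one global seed; each generator stage derives its own stream
  (`7·seed + stage offset`), so equal configurations are bit-identical and
  nearby seeds never share a stream across stages.

What the generator does *not* emulate: raw LRR/BAF intensities, linkage
disequilibrium (the PRS is an abstract standardised score), platform batch
structure, and population stratification correlated with burden. Passing
tests therefore demonstrate the pipeline's arithmetic and statistical
calibration under the stated model, not robustness to intensity-level
artefacts.

## Statistical model choices

* **Mixed phenotype scales.** Case/control cohorts contribute logistic
  log-odds estimates directly alongside the 0–1-scale linear estimates,
  under the interpretation of case status as a censored observation of the
  latent symptom scale; no rescaling is applied. Their large standard
  errors give them correspondingly small IVW weight.
* **Ordinal odds ratios.** For interpretability, score cohorts can be
  re-analysed with a proportional-odds model on raw integer levels
  (decile bins when more than 50 distinct levels, bounding the parameter
  count); odds ratios are meta-analysed on the log scale without
  rescaling.
* **Robust sensitivity.** `fit_hc3()` reproduces the identical coefficient
  with HC3 sandwich standard errors, the appropriate check when a term is
  driven by a handful of carriers; an observation with leverage 1 makes HC3
  undefined and is reported as an error rather than patched.
* **Inestimable cohorts** (zero carriers, collinear designs) are flagged
  and excluded from the meta-analysis — IVW weights are undefined for them
  — with the reason retained.
* **ΔR² standard errors.** The PRS/CNV joint model reports incremental R²
  per increment with the large-sample variance formula
  `Var(R²) ≈ 4R²(1−R²)²(n−k−1)²/((n²−1)(n+3))` applied to the increment,
  and an exact F-test p-value. The large-sample form can understate
  uncertainty in small cohorts; the F-test is authoritative there.
* **Families for FDR.** Genome-wide span terms form one family; NDD
  carrier terms one family per overlap rule; genes one family; gene-sets
  one family per type stratum. Normal-theory p-values are used throughout
  the meta-analysis (no small-k t correction), matching standard IVW
  practice.

## Validation strategy and problem sizes

The test suite validates each layer against an implementation-independent
oracle: consensus intersection against per-basepair AND masks on ≤100 kb
toy genomes (1000 random fixtures), annealing against an exhaustive
re-merging oracle, coverage fractions and gene indicators against
brute-force scans, BH q-values against the step-up definition on all
subsets of an 8-value panel, HC3 against the definitional sandwich on a
fixed 6-point design, and IVW against both its closed form and
`metafor::rma(method = "FE")`.

Statistical behaviour is validated by simulation at sizes chosen to keep
the full suite in the minutes range: size of the burden and meta z-tests
under the planted null (5 cohorts × 150 subjects, 1000 phenotype
replicates on a fixed burden design; empirical rejection within
[0.036, 0.064] at α = 0.05), recovery of the planted 0.03/Mb NDD-deletion
effect through the *complete* pipeline (200 replicate studies of 5 × 1000
subjects; mean within 10%, 95% CI coverage within [0.92, 0.975]), and
set-specific enrichment (planted set detected in ≈99/100 replicates, a
size-matched random control set at the nominal false-positive rate). The
pinned-fixture QC test freezes every record count of a seeded study, so any
behavioural drift in consensus or filtering fails loudly.

A small measurement-attenuation effect is visible in recovery runs:
boundary jitter shrinks consensus intervals slightly and type flips remove
a few true carriers, leaving the mean recovered effect a few percent away
from the planted value — the expected behaviour of consensus calling, not
an estimator defect.

## Known limitations

* Two callers only; three-way consensus is out of scope.
* Frequency filtering uses the post-consensus, pre-filter callset jointly
  over cases and controls; no stratified frequency option is provided.
* The aneuploidy fraction is computed on the consensus set before CNV-level
  filters; the alternative ordering is untested.
* Annealing after intersection is the implemented order; annealing each
  caller's set before intersection is a plausible alternative that was not
  implemented.
* Dual-caller fragmentation at independent positions can occasionally leave
  a true event split at the annealing fixed point; only single-caller
  fragmentation carries a recovery guarantee.
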