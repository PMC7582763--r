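---
title: "Methods: hypomethylation biomarker discovery and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypomethylation biomarker discovery and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylomark)
```

# Scope and model

methylomark implements the analysis chain of a tumor-marker methylation
study on paired tissues: per-probe differential summaries of array beta
values, strict three-criterion filtering intersected across two discovery
cohorts, ΔΔCt fold-ratio calls for qPCR assays, plasma cell-free DNA
(ccfDNA) diagnostics, contingency/correlation analysis against clinical
covariates, and product-limit survival stratified by the methylation call.
Every stage can run from files (TSV/CSV in the package's data model) or
from a seeded synthetic cohort with planted truth.

A beta value is the methylated fraction of an interrogated CpG, in
[0, 1]. Probes carry a signed offset from the transcription start site;
the sign alone determines the region class (negative = promoter,
nonnegative = gene body), because signed offsets are all the upstream
analysis needs — no genome assembly coordinates are invented.

# Discovery

For each probe, `summarize_probe()` reports Avg\_β(N), Avg\_β(T) over the
paired samples (pairwise-complete: a pair with either member missing is
dropped, never imputed) and ΔAvg\_β = Avg\_β(T) − Avg\_β(N), exactly.
Candidate filtering uses three strict predicates, all tunable via
`discovery_criteria()`:

| parameter    | default | meaning |
|--------------|---------|---------|
| `delta_max`  | −0.25   | ΔAvg\_β must be below this (β difference) |
| `normal_min` | 0.5     | normal tissue must be well methylated |
| `tumor_max`  | 0.2     | tumor tissue must be lowly methylated |

Design choices that were genuinely open, and how they were resolved:

* **Gene-level aggregation.** A gene is selected when *any* of its probes
  passes — single-CpG markers are exactly the discovery target here, and
  an all-probes rule would discard genes whose differential signal is
  confined to one site (typical of gene-body hypomethylation).
* **Two-cohort intersection.** The passing probe need not be the same in
  both cohorts; the claim being confirmed is about the gene. The reported
  best probe prefers probes that pass in every contributing cohort.
* **Paired test.** The Wilcoxon signed-rank test is the primary p-value
  (exact null up to 25 usable pairs, normal approximation above, which is
  also where ties make the exact null unavailable); a paired t-test is
  reported alongside. Selection itself uses only the β criteria —
  p-values are descriptive, raw plus Benjamini–Hochberg.
* **Missingness.** Probes with more than 20% of pairs unusable are
  excluded from selection (`max_missing_fraction`); below that, means are
  computed on the complete pairs.
* **Ranking.** Ascending minimum tumor Avg\_β over the gene's passing
  probes, ties broken by descending normal Avg\_β, then gene symbol —
  deterministic and aligned with "lowest in tumor, highest in normal"
  being the strongest marker.

Degenerate inputs: identical normal/tumor vectors give Δ = 0 and p = 1; a
numerically constant nonzero difference short-circuits the t-test to 0
rather than erroring inside `t.test`.

# Relative quantification

`relative_level()` is `base^−(Ct_target − Ct_ref)` with `base = 2`
(100% amplification efficiency) by default; the base is exposed because
efficiency-corrected analyses use values near 1.9–2.1. Technical
replicates are aggregated by the arithmetic mean of Ct before the
transform. The paired fold ratio then equals `base^−ΔΔCt`; the test suite
verifies this identity against the closed form on random Ct tuples.

Class boundaries are strict: ratio < 0.5 → hypo (low), ratio > 2 → hyper
(high), otherwise equal (moderate). A ratio exactly at a boundary is the
middle class; boundary values essentially never occur in continuous data,
so the choice only pins down the semantics. Zero levels are flagged
(`ratio_defined = FALSE`) and classified conservatively (both zero →
equal; zero normal with positive tumor → hyper) — never epsilon-adjusted.

Cohort percentages are computed at full precision from class counts and
*displayed* to one decimal; comparisons against externally printed
percentages should allow ±0.1 points, since one-decimal renderings mix
truncation and rounding in the wild.

# Plasma diagnostics

A plasma subject is positive — hypomethylated, the disease-indicating
state — when its relative level is strictly below an absolute cutoff
(default 0.5). The cutoff is deliberately an absolute level rather than a
fraction of the healthy mean (≈ 25.4, kept as metadata): one rule, no
hidden second normalization. With disease = CRC, sensitivity = TP/(TP+FN)
and PPV = TP/(TP+FP); metrics with empty denominators are flagged
undefined, never reported as 0. Group association is tested two ways —
Fisher's exact test on the calls and a Welch t-test on log levels — since
a dichotomized and a continuous view of the same cohort answer slightly
different questions. `threshold_sweep()` evaluates a cutoff grid;
sensitivity is nondecreasing and specificity nonincreasing in the cutoff
by construction, which the tests check on random cohorts.

# Clinical association and survival

Contingency tables use the uncorrected Pearson χ² (the convention of
SPSS-style clinical tables); Yates correction sits behind a flag, default
off. Empty margins are dropped with a warning; a table that collapses
below 2×2 is an error. Stratifications mirror common clinical reporting:
age dichotomized at 65, stage 0–I vs II–IV, tumor size T0–T1 vs T2–T4,
nodal/distant status 0 vs ≥ 1. Patients missing a covariate are excluded
from that parameter's breakdown only. Across parameters, raw p-values are
reported; a Benjamini–Hochberg column can be derived by the caller from
the returned tests.

Survival uses the product-limit estimator and the 1-df log-rank test (via
the survival package), with the standard simultaneous-death handling of
tied event times. Patients are dichotomized as hypo vs non-hypo from
their fold-ratio call; subgroup analyses filter on age > 65, male sex, or
stage III–IV before comparison. With no events at all, the log-rank
statistic is flagged undefined.

# What the synthetic cohorts emulate

The generators define the study conditions the package is tested under:

* **Methylation arrays** (`methylation_sim_config`): 26 tumor/normal
  pairs per cohort (a typical discovery-array cohort size), 20 genes × 5
  probes, planted hypomethylated genes at normal mean β 0.55 and tumor
  mean β 0.12 — the regime the default criteria are designed to detect —
  with all other genes sharing a per-gene baseline in both tissues. Beta
  values are Beta-distributed, parameterized by mean and concentration
  (default 60, i.e. SD ≈ 0.06 at β = 0.5), which guarantees [0, 1]
  support; 2% of cells are masked missing.
* **QMSP Ct tables** (`qmsp_sim_config`): 548 pairs with class fractions
  0.914 / 0.036 / 0.05 (hypo / equal / hyper), the hypomethylation
  prevalence regime of a large CRC tissue cohort. Ct values are built as
  the exact inverse of the ΔΔCt transform — reference at 25 cycles,
  target at reference + implied ΔCt — with Normal per-replicate noise
  (default SD 0.15 cycles, three replicates). Fold ratios are drawn away
  from the 0.5/2 boundaries, so at zero noise the pipeline recovers the
  planted class exactly, and recovery degrades smoothly as noise grows.
  The noise default is chosen for test stability; no variance for such
  assays was available to calibrate against.
* **Plasma** (`plasma_sim_config`): 15 + 15 subjects; true positives
  uniform below the 0.5 cutoff, healthy negatives log-normal around a
  mean level of 25.37, CRC negatives between 2× the cutoff and the
  healthy mean. `crc_positive_fraction` (default 0.87) and
  `healthy_positive_fraction` (default 0) set detection and
  false-positive regimes; the latter is an extension knob for emulating
  noisy small-volume extraction protocols.
* **Clinical/survival** (`survival_sim_config`): 548 patients,
  hypomethylation prevalence 0.914, exponential event times at baseline
  hazard 0.01/month (≈ 55% five-year survival in the reference group)
  with a hazard ratio of 2 for the hypo group — a moderate adverse effect
  chosen because no numeric hazard estimate was available, only the
  direction — independent exponential censoring targeting 30%, and
  covariates at 54% age > 65, 59% male, 55% stage III–IV.

What the generators deliberately do **not** emulate: bisulfite-conversion
error, probe cross-hybridization, batch effects, amplification-efficiency
drift, or correlated missingness. Passing tests therefore demonstrate
that the analysis machinery is correct and calibrated under clean
planted-truth conditions, not that it is robust to every artifact of real
array or qPCR data.

# Problem sizes and determinism

The test suite and the acceptance script run at the sizes above: 548-pair
quantification and survival cohorts, 26-pair two-cohort discovery over 20
seed replicates, 100-replicate null calibrations for the log-rank test
(level 0.05 ± 0.05) and small exhaustive enumerations (all 2×2 tables
with total ≤ 30 against the textbook χ² formula). The full synthetic
pipeline completes in about a second on one CPU.

All randomness flows through R's default Mersenne-Twister generator,
seeded locally per generator call; the caller's RNG state is saved and
restored, so identical configs give identical outputs wherever they run.

# Interfaces

The R functions are the primary interface; `run_pipeline()` +
`pipeline_config()`/YAML orchestrate the stages end to end, and a thin
Rscript front end (`inst/scripts/methylomark.R`) exposes `simulate`,
`discover`, `quantify`, `plasma`, `associate`, `survival` and `run`
subcommands over exactly those functions.

# Known limitations

* Discovery reports candidates from the provided matrices only; it makes
  no attempt to reproduce genome-scale candidate counts, which depend on
  the full array content and cohort composition.
* Amplification efficiency is a single global base; no per-assay standard
  curves.
* No Cox regression or competing risks — group comparison is log-rank
  only.
* The plasma module ignores extraction-protocol batch effects; cohorts
  from different protocols should be evaluated separately.
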