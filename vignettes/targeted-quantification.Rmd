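---
title: "Internal-standard response-factor quantification for plant LC-HRMS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard response-factor quantification for plant LC-HRMS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroquant)
```

## The problem

Quantifying trace pharmaceuticals in plant tissue by targeted LC-HESI-HRMS
runs into two systematic obstacles: electrospray ionization responds to the
co-extracted matrix (suppression or enhancement of the analyte signal that
differs between, say, spinach leaf and arugula root), and extraction losses
vary sample to sample. The standard remedies are isotopically labeled
internal standards (IS) added at a fixed amount to every sample before
extraction, and matrix-matched standards (MST) — calibration standards
prepared in blank tissue extract instead of solvent. `aeroquant` implements
the complete computation layer of such a method: it consumes peak-area
tables (peak detection and integration are vendor-software territory and out
of scope) and produces calibrated concentrations, per-sample detection
limits, method-validation statistics and an uptake-analysis summary.

## The model

For compound $i$ at calibration level $c$ the **response factor** is

$$ RF_{i,c} = \frac{A_{NS}/A_{IS}}{C_{NS}/C_{IS}}, $$

with $C_{IS}$ = IS amount / extract volume (5 ng in 1 mL by default, so
5 ng mL$^{-1}$). The **average response factor** $ARF_i$ is the mean over
*retained* levels and is the default quantifier; concentration is recovered
by inversion, $C_{NS} = (A_{NS}/A_{IS})\,C_{IS}/RF$. Because the IS is
carried through extraction and ionization with the analyte, both extraction
losses and drift in overall instrument sensitivity cancel in the area ratio.

**Calibration trimming.** A level is excluded when its RF deviates by
30 % or more from the ARF. The published rule does not say whether the
exclusion is single-pass or iterative, so the package fixes a deterministic
procedure: repeatedly drop the single worst-deviating level (ties break
toward the lower concentration, where failures concentrate in practice) and
recompute the mean; after convergence any excluded level that now sits
inside the band is re-admitted. The result is a fixed point — every
retained level deviates strictly less than the threshold from the retained
mean, every excluded level at least the threshold — and is independent of
input order. At least three levels must survive or the calibration is
invalid. Linearity ($r^2$ of the area ratio against concentration,
unweighted least squares over retained levels) is reported as a diagnostic
only; quantification always goes through the ARF, so a saturated top level
shortens the reported linear range without biasing lower concentrations.

**Matrix effects.** For each compound × tissue with a matrix-matched
standard (spiked at the top calibration level),

$$ ME = \frac{RF_{MST} - ARF}{ARF} \times 100\,\%, $$

negative meaning suppression. When $|ME|$ *strictly exceeds* 20 %, the
$RF_{MST}$ replaces the ARF for that compound in that tissue. The
strictness matters at the boundary: $ME = -20.0$ keeps the ARF.

**Per-sample LOQ/LOD.** The NS peak area of the *lowest retained*
calibration level, divided by 2, is substituted into the quantification
chain in place of the sample's NS area — but together with the sample's own
IS area, quantifier and preparation constants. A sample with half the IS
recovery therefore has twice the LOQ, and a suppressed matrix raises it
further; with neutral IS and matrix, a 0.5 ng mL$^{-1}$ lowest level, 1 mL
and 50 mg the LOQ is 5 ng g$^{-1}$ dry weight. LOD is LOQ/3 (the ratio is
implied by published LOQ/LOD tables in this field, with values printed at 2
significant figures). Concentrations below the sample's LOQ are reported as
`"<LOQ"` with the numeric value retained. Tissue concentrations follow
$C_{tissue} = C_{extract} \cdot V / m$ (1000 ng mL$^{-1}$ → 20 000
ng g$^{-1}$ dw at 1 mL / 50 mg).

## Validation statistics

Recovery at a spike level is $(measured - background)/spike \times 100$,
with the background taken as the mean of uncensored control samples of the
same tissue (zero when all controls are censored — the published procedure
fortifies control samples but states no subtraction rule, so the package
states one). Precision is the sample ($n-1$) RSD. The solvent-comparison
summary averages recoveries and per-compound RSDs over compounds and rounds
half-away-from-zero to integer percent — half-to-even rounding does not
reproduce conventionally rounded printed tables (a mean RSD of exactly
2.5 % prints as 3 %). Robustness over an injection sequence compares the
first and last calibration level by level: the ratio $RF_{last}/RF_{first}$
must stay within a 30 % band around 1.

## The synthetic world

No raw data accompany the method, so a seeded generator emulates the study
design: nine calibration levels 0.1–1000 ng mL$^{-1}$, one matrix standard
per tissue at the top level, heptaplicate spiked QCs at 10/100/1000
ng g$^{-1}$ dw, triplicate controls, 50 mg / 1 mL / 5 ng IS, and optional
unknown groups with true tissue concentrations. Areas follow

$$ A_{IS} = A_0\, \rho_{IS}\, d(t)\, \varepsilon, \qquad
   A_{NS} = RF^{true} \frac{C_{extract}}{C_{IS}} A_0\, s(\textrm{tissue})\,
            d(t)\, g(t)\, \varepsilon', $$

with $A_0 = 10^6$ counts, IS recovery $\rho_{IS}$, matrix factor $s$ acting
on the NS area only, IS recovery on the IS area only (so the two corrections
are testable independently), and independent lognormal noise
$\varepsilon$ with mean 1 and stated CV (areas are positive and CVs are the
natural error scale; default 5 %, the typical replicate RSD of the method).
Two drift terms exist because they are physically distinct: $d(t)$ is a
shared sensitivity ramp that cancels in every RF — which is exactly why
isotope-dilution quantification is robust over a 170-injection sequence —
while $g(t)$ acts on the NS area only and produces genuine RF drift, the
quantity a first-versus-last calibration comparison measures. A
specification that applies one common drift to both areas would make RF
drift unobservable by construction. Defaults: no drift; the drift scenario
uses $g$ = 1 %-per-10-injections, giving an end-to-end ratio of
$1.01^{16.1} \approx 1.17$ over indices 0–169, inside the 30 % band.

Default world, chosen once: compound RFs spread over 0.3–1.2 with
metabolites at the low end (mirroring their weak electrospray response);
matrix factors 0.70 (spinach leaf), 0.90 (spinach root), 1.25 (arugula
leaf), 1.10 (arugula root), 0.85 (pea leaf) — stronger effects in green
tissue than roots, with both corrected (|ME| > 20 %) and uncorrected cases
represented; extraction and IS recovery 1.

**What a green test establishes.** The generator reproduces the *structure*
of the design — IS normalization, matrix-effect geometry, drift, lognormal
replicate scatter — not the chemistry: no retention-time behaviour, no
compound-specific ionization physics, no real blank-matrix variability, no
correlation between a compound's matrix effect and its response. Parameter
recovery on this world validates the computation chain, not the analytical
method itself.

## Numerical and design choices

* **Decision boundaries are strict** where the published wording is strict
  ("exceeded 20 %"): $|ME| = 20$ keeps the ARF; a calibration deviation of
  exactly the threshold drops the level; censoring uses strict `<`.
* **Replicate calibration sets** (first and last of a sequence) are averaged
  per level before trimming when calibrating for quantification; drift
  assessment fits them separately (`calibrate(..., sample_ids = )`,
  `split_calibration_sets()` cuts at the largest acquisition-index gap).
* **Zero IS area** marks an injection invalid; nothing is imputed, because
  IS normalization is undefined without the IS area.
* **Censored values** never enter uptake ratios or leaf fractions; groups
  with a censored side report a reason code instead of an LOQ/2 surrogate —
  simple and auditable, and no published rule says otherwise.
* **Ionization fractions** use the monoprotic Henderson–Hasselbalch form
  with a single "strongest" pKa per compound (6.16 acidic for the
  sulfonamide, 7.55 basic for the lincosamide), as the field's uptake
  reasoning does, even where compounds are amphoteric.
* **The benchmark's estimand** (`recovery_benchmark()`) is the method's
  noise-free asymptote *conditional on the quantifier decision actually
  taken*: residual matrix bias under a retained ARF is a property of the
  20 % decision rule, not an estimation error. With noise-free generation
  all reported relative errors are exactly zero under this definition.
* **Boundary instability, a known limitation.** When a true matrix effect
  sits near the 20 % threshold (e.g. −15 % with ~7-point noise on the
  single-injection $RF_{MST}$ at CV = 5 %), the quantifier decision itself
  flips between repetitions, and the conditionally selected $RF_{MST}$ is
  biased (it triggered *because* it strayed). The stability benchmark is
  therefore run in a matrix-neutral world; the flip phenomenon is inherent
  to single-injection matrix-matched correction with a hard threshold, and
  replicating the matrix standard would be the methodological fix.

## A worked run

```{r, eval = FALSE}
truth  <- simulation_truth(cv = 0.05, seed = 42)
tables <- simulate_experiment(truth, study_design(second_calibration = TRUE))
models <- calibrate(tables)
me     <- matrix_effects(tables, models)
res    <- quantify_samples(tables, models = models, me = me)
recovery_table(res, tables$samples)
sets  <- split_calibration_sets(tables$samples)
rf_drift(calibrate(tables, sample_ids = sets$first)[["carbamazepine"]],
         calibrate(tables, sample_ids = sets$last)[["carbamazepine"]])
```

The same pipeline is scriptable end to end through the `aeroquant()` command
line (`simulate`, `quantify`, `validate`, `uptake`, `report`), with exit
codes 0/2/3 for success, schema failure and invalid calibration.
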