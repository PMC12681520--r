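---
title: "Targeted quantification of uremic toxins and bile acids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted quantification of uremic toxins and bile acids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmquant)
```

## What the package computes

`gmmquant` is a pipeline for targeted LC-MS/MS quantification of gut
microbiota-derived metabolites — uremic toxins (UTs) and bile acids (BAs) —
in plasma and feces, aimed at cohort comparisons such as peritoneal-dialysis
(PD) patients versus healthy controls (HC). It starts where vendor software
stops: from integrated MRM peak areas, one row per sample x analyte x
dilution. The stages are

1. **Panel registry** — the analyte panel, internal-standard (IntStd)
   assignments, conjugate quantification groups and exclusion rules.
2. **Matrix-matched calibration** — weighted least squares of the response
   ratio (analyte area / IntStd area) on nominal concentration, per analyte
   and per specimen matrix; LOD/LOQ from low-level residuals.
3. **Back-calculation** — inversion of the curve per record, selection of
   one reported value across each sample's serial dilutions, and conversion
   from extract to specimen units.
4. **Method validation** — intra-/inter-day precision (%RSD), spike
   recovery, matrix effect, with pass/fail flags.
5. **QC cascade** — exclusions, conjugate collapsing, the 80% detection-rate
   filter, group-minimum imputation, the 80-120% IntStd recovery gate with
   group-median imputation.
6. **Cohort statistics** — age/sex-adjusted linear models per metabolite,
   exact Mann-Whitney subgroup tests with Holm-Šidák correction, chi-square
   on the sex table, Spearman/Benjamini-Hochberg correlations, composition
   profiles, PCA, and the fecal/plasma partition of significant metabolites.

A synthetic-data module generates cohorts, true concentrations and
instrument responses with the statistical structure the analysis assumes, so
every stage is testable without instrument data.

## The calibration model

For analyte $a$ in matrix $m$, standards at nominal concentrations $x$
(default ten points, serially diluted over 0.005–20 µM; a twelve-point
variant is available for validation designs) yield response ratios
$y = A_a / A_{\mathrm{IS}}$. The curve is

$$ y = \beta_0 + \beta_1 x + \varepsilon, \qquad
   \operatorname{Var}(\varepsilon) \propto 1/w(x), $$

with $w(x) = 1/x$ by default. Weighting $1/x$ is the common choice for
calibration ranges spanning three to four decades, where absolute residual
magnitude grows with concentration; unweighted and $1/x^2$ fits are
selectable. $R^2$ is computed on the fitted (weighted) scale and a curve
below 0.99 is flagged. Back-calculation inverts the line and multiplies by
the dilution factor; a value below $\mathrm{LOQ} \times$ dilution is kept as
a censored marker, never as a number — the QC cascade decides what happens
to it.

**LOD/LOQ.** The estimator is ICH-style: $\mathrm{LOD} = 3.3\,s/|\beta_1|$
and $\mathrm{LOQ} = 10\,s/|\beta_1|$, where $s$ is the residual standard
deviation over the lowest six distinct levels. Their ratio is exactly
$10/3.3$ by construction, which the tests assert. A perfect (noise-free)
line gives LOD = LOQ = 0.

**Dilution selection.** Each specimen is injected as a serial-dilution
series (plasma neat, 1:1, 1:49; feces neat, 1:1, 1:9). The reported value is
the least-diluted record whose vial-scale response lies inside the
calibration range; if every quantifiable record exceeds the range the most
diluted one is used, and if nothing is quantifiable a censored marker is
reported. This rule is a package design choice: the assay prepares the
dilutions but no selection rule is published, and least-diluted-in-range
maximizes signal-to-noise while avoiding extrapolation.

**Units.** Extraction arithmetic fixes the conversion constants: 100 µL
plasma in a 1 mL extract gives specimen µM = extract µM × 10; 250 mg feces
in 2 mL gives µmol/g = extract µM × 0.008.

**Matrix effect with ratio-based curves.** Because calibration is on
response ratios, the slope ratio of matrix-matched to neat curves measures
the analyte's ion suppression *relative to its internal standard's*. This is
the quantity `%ME` reports; it equals the absolute multiplier only when the
IntStd is unsuppressed. The validation tests use this relative quantity as
their oracle.

## The QC cascade

The order is fixed and logged in the matrix's audit trail:

1. drop panel-excluded analytes (defaults: GCA, CDCA, GB, which accumulate
   on the column);
2. collapse co-eluting conjugated BAs into taurine- and glycine-conjugate
   sums (TCDCA+TDCA+TUDCA, GCDCA+GDCA+GUDCA); the summed cell is `measured`
   only if all members are, otherwise it takes the weakest member's
   provenance;
3. detection-rate filter: an entity is kept only if detected in at least 80%
   of samples *in every group* ("fewer than 80%" excludes, so exactly 80% is
   retained). "Detected" means a quantifiable value at or above the LOQ;
4. group-minimum imputation of the remaining censored/absent cells;
5. IntStd gate: per sample and ESI mode, the back-calculated IntStd
   concentration is compared with the nominal spike (10 µM ESI⁻, 1 µM ESI⁺);
   recovery strictly below 80% or above 120% flags the sample, and all of
   its cells are replaced by medians of the non-flagged samples of its group.

Minimum-imputation precedes the gate's median-imputation, matching the order
in which the rules are stated for the assay. Donor pools for the median
exclude other flagged samples. Imputation groups are always clinical group
within matrix. Re-running the cascade on its own output is a no-op; for that
to hold, median-imputed cells count as detections (they replaced valid
measurements) while min-imputed cells do not.

## Statistics

Concentrations are log-transformed before the linear model
$\log c = \alpha + \beta\,\mathrm{PD} + \gamma\,\mathrm{age} +
\delta\,\mathrm{sex} + \varepsilon$ (configurable to the raw scale);
metabolomic concentrations are right-skewed and the group effect is then a
log fold-change. Age enters linearly. The 2x2 chi-square is Pearson's
without continuity correction — the convention that reproduces the printed
sex-table p-value (0.00677) from its counts. Holm-Šidák (step-down,
$\tilde p_{(i)} = \max_{j \le i} 1-(1-p_{(j)})^{m-j+1}$) and
Benjamini-Hochberg (step-up, $\tilde p_{(i)} = \min_{j \ge i} m p_{(j)}/j$)
are implemented from their definitions and cross-checked against brute-force
oracles and `p.adjust`. The Mann-Whitney test enumerates the full
permutation distribution of $U$ for groups of at most eight and otherwise
uses the tie- and continuity-corrected normal approximation. The MAD in
`median_mad_summary` is raw (no 1.4826 factor), matching the clinical-table
convention "median ± MAD". Spearman correlations use pairwise deletion,
because clinical variables are unevenly available between cohorts.

### A caution on age adjustment

The two cohorts are strongly age-separated (HC median 22, PD median 58).
Group and age are therefore collinear in the adjusted model, which inflates
the group-coefficient standard error roughly threefold relative to an
age-balanced design. The estimate remains unbiased — the type-I calibration
and effect-recovery tests confirm this — but power is paid for the
adjustment. This mirrors the real design's limitation and is why the
subgroup Mann-Whitney analysis restricted to comparable ages exists as a
companion.

## The synthetic-data generator

The generator encodes the study conditions: 60 HC vs 31 PD; ages drawn from
scaled Beta distributions with supports [19, 57] and [29, 82] and medians
near 22 and 58; sex proportions 56.1% / 25% female; PD comorbidity
probabilities 0.357 (DM only), 0.571 (DM and/or CVD), 0.072 (neither). True
concentrations are log-normal per analyte x matrix x group — the standard
model for between-subject metabolite variation — with a multiplicative PD
fold-change and a per-matrix detection probability. Instrument response is
linear with per-analyte slope, per-analyte x matrix ion-suppression
multiplier (defaults within [0.4, 1.419]; values as extreme as 0.004 are
admissible), intra-day, inter-day (a day-level random effect shared by all
injections of a day) and injection variance components, area censoring below
a threshold, and occasional whole-sample suppression that drags analyte and
IntStd areas down together — the failure mode the IntStd gate exists to
catch.

Default parameter choices, made once:

- **Composition targets.** HC plasma is dominated by lithocholic acid
  (~94% of the summed mean), PD plasma by phenyl sulfate (~44%), indoxyl
  sulfate rises ten-fold: the plasma medians and fold-changes (PS 28, IS 10,
  LCA 0.4) are the solution of that composition arithmetic. Absolute medians
  are stylized — they are placed so each detected analyte falls inside the
  calibration window at one of the assay's dilutions, not to be
  physiological.
- **Plasma LCA direction.** The default is *lower* in PD (fold 0.4),
  consistent with the composition shift; fecal LCA is higher. Reports about
  this analyte's direction conflict, so it is an ordinary parameter.
- **Biological geometric CV 0.5 and designed fold-changes ≥ 3.** With the
  age-collinearity noted above, the group-coefficient SE at n = 60/31 is
  about 0.30 on the log scale. A geometric CV of 0.5 keeps a 3-fold effect
  detectable with power above 0.9 — the calibration the generator is
  required to satisfy — while staying in the realistic range for
  between-subject metabolite variation.
- **Variance components.** Intra-day CV 5%, inter-day 8%, injection 2%:
  simulated intra-/inter-day %RSDs fall inside the 1–19% band reported for
  assays of this class.
- **Detection structure.** Twelve analytes are detectable in plasma and
  twenty in feces (feces carrying the broader BA diversity); detection
  probabilities are 1 or 0 by default so the detection filter's behaviour is
  exactly predictable, and intermediate probabilities are exercised in the
  tests.
- **Suppression.** 4% of samples, factor uniform on [0.3, 0.7] — enough to
  exercise the gate without distorting the cohort.

What the generator does *not* emulate: chromatography (no retention times or
peak shapes), carryover, batch drift beyond the day effect (the assay
randomizes injection order instead), correlated metabolite networks, or
non-log-normal tails. Passing tests therefore demonstrate that the pipeline
implements its rules correctly and recovers known truth under the stated
error model — not that any particular real-data result would replicate.

## Numerical choices and degenerate inputs

- Calibration needs at least five usable distinct levels; fewer is a
  *calibration failure* carried along as a status, not an error.
- Zero slope makes LOD/LOQ undefined (flagged); zero replicate mean makes
  %RSD undefined (flagged).
- Ties in the Mann-Whitney statistic are half-counted; exact enumeration is
  used only up to eight per group (12,870 arrangements at 8 vs 8).
- A constant entity yields a flagged, NA test rather than an error.
- All randomness flows through named seeds (`withr::with_seed`), so no call
  mutates global RNG state; per-stage seeds are derived from the master seed.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline at the
study's sample sizes (60/31), the round-trip identity on a 6+5-subject
cohort (every analyte, matrix and dilution), the null-calibration suite on
1,000 simulated null metabolites, and effect-recovery on twelve pipeline
replicates. These sizes were chosen as the smallest that make the Monte-Carlo
assertions sharp.

## Known limitations

- The LOD/LOQ recipe is one published convention (3.3σ/S, 10σ/S on
  low-level residuals); signal-to-noise- or blank-based estimators would
  give different absolute values. Alternative estimators can be slotted in
  via `estimate_lod_loq`'s interface.
- `%ME` is relative to the internal standard's own suppression (see above).
- The pipeline starts from integrated areas; nothing upstream of peak
  integration (raw spectra, retention alignment) is modelled.
- Only the two imputation rules of the described cascade are provided —
  no model-based imputation.
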