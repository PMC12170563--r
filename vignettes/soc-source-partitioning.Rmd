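---
title: "Partitioning soil organic carbon into plant and microbial sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning soil organic carbon into plant and microbial sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socsource)
```

## The problem

Bulk soil organic carbon (SOC) mixes residues of very different origin:
structural plant polymers that survive decomposition, and the cell-wall
remains of dead fungi and bacteria ("necromass") accumulated through
microbial turnover. Which source dominates, and which soil properties
control each, determines how stable a soil's carbon is and how it responds
to land-use change — for example the widespread conversion of subtropical
broadleaf forest to Moso bamboo plantations.

Neither source can be measured directly, so both are inferred from
biomarkers:

* **Lignin phenols.** Alkaline CuO oxidation releases eight phenolic
  monomers found only in plant tissue. They fall into three structural
  classes — vanillyl (V: vanillin, acetovanillone, vanillic acid), syringyl
  (S: syringaldehyde, acetosyringone, syringic acid) and cinnamyl (C:
  p-coumaric acid, ferulic acid). The acid-to-aldehyde ratios within the V
  and S classes, (Ac/Al)v and (Ac/Al)s, rise as lignin is oxidised, so they
  index the degradation state of the plant residue pool.
* **Amino sugars.** Glucosamine (GlcN) derives chiefly from fungal chitin,
  muramic acid (MurN) exclusively from bacterial peptidoglycan, and
  galactosamine (GalN) contributes to the total amino-sugar pool.
  Conversion factors turn these into fungal and bacterial necromass carbon.

## The attribution model

With monomer concentrations in mg per kg dry soil and pools in g per kg,
the package computes

$$C_\text{plant} = \frac{1}{1000}\left(\frac{V}{0.33} + \frac{S}{0.9} +
  \frac{C}{0.03}\right),$$

$$C_\text{fungal} = \left(\frac{\mathrm{GlcN}}{179.17} -
  2\,\frac{\mathrm{MurN}}{253.23}\right) \times 179.17 \times
  \frac{9}{1000}, \qquad
  C_\text{bacterial} = \mathrm{MurN} \times \frac{45}{1000},$$

with microbial-derived C the exact sum of the fungal and bacterial pools,
and each pool also expressed as a percentage of SOC. 179.17 and 253.23 are
the relative molecular weights of GlcN and MurN; 9 and 45 the conventional
necromass conversion factors; the factor 2 removes the bacterial
contribution to glucosamine (two moles of GlcN per mole of MurN in
peptidoglycan); and 0.03 encodes the minimal (3%) lignin content of the
principal plant residues.

Two numerical choices deserve comment.

*The plant-carbon formula.* The commonly printed form of the lignin-based
plant-C formula string multiplies the coefficient-weighted phenol sum by
"SOC × 100%", which is not dimensionally a percentage. We compute the
absolute pool $C_\text{plant}$ (g/kg) from the weighted sum alone and
report the SOC share as $100 \times C_\text{plant}/\mathrm{SOC}$. This
preserves the published class coefficients, produces a bona fide
percentage, and reproduces the published fractions (8.38% of SOC in
broadleaf, 21.31% in Moso bamboo soil) and their 2.22x pool ratio. All
coefficients are arguments of `attribution_coefficients()`, so alternative
readings are one configuration change, not a code change.

*Negative fungal carbon.* In strongly bacterial profiles the GlcN
correction can go negative. The raw value is kept and flagged
(`negative_fungal_c`) rather than truncated — silent truncation would bias
group means — while fraction-of-SOC computations clip at zero and record
the clip through the same flag. Degenerate lignin inputs (zero vanillin or
syringaldehyde, zero total lignin) likewise yield `NA` plus a QC flag
instead of an error. Rounding happens only at the reporting layer.

```{r attribution}
plots <- generate_paired_dataset(default_config(), seed = 42)
att <- attribute_table(plots)
round(att[1:4, c("lignin_total", "ac_al_v", "plant_c", "fungal_c",
                 "bacterial_c", "microbial_c", "microbial_fraction")], 2)
```

## The synthetic study design

`default_config()` encodes a paired-plot field design: 11 pairs of adjacent
20 x 20 m plots, one broadleaf and one Moso bamboo plot per pair, matched
for topography, each variable carrying a pair-level random effect shared by
the two plots of a pair. Per variable the generator draws

> forest mean + pair effect + residual,

on the log scale for strictly positive concentrations (lognormal,
moment-matched so the expectation equals the configured mean — this avoids
negative draws at realistic spreads), on the natural scale for pH (normal)
and for bounded percentages (truncated normal).

The configured means are not free knobs; they are derived once from the
reported group values of the study design the generator emulates:

* SOC means (17.99 / 15.72 g kg⁻¹) are back-calculated from the reported
  microbial pools (9.18 + 1.21 and 6.85 + 0.93 g kg⁻¹) divided by the
  reported microbial fractions of SOC (57.75% / 49.49%); the implied SOC
  contrast is a 12.6% reduction under bamboo.
* GlcN and MurN means are exact algebraic inversions of the necromass
  formulas at those pool values. The Moso GalN mean (400 mg kg⁻¹) is an
  assumption in the realistic range of roughly half the GlcN pool; the
  broadleaf GalN mean is then solved so the expected broadleaf/Moso total
  amino-sugar ratio is exactly 1.2843 (a 28.43% excess).
* Total lignin means follow from the plant-C fractions (8.38% / 21.31% of
  SOC), split into V/S/C classes at 56.30/15.09/28.61% (broadleaf) and
  54.46/14.72/30.82% (Moso) — the implied Moso/broadleaf lignin ratio is
  about 2.1, "more than twice". Within classes, monomers are split with a
  fixed 25% ketone share and acid/aldehyde shares set by target (Ac/Al)
  values chosen higher in broadleaf (0.65 vs 0.45 for V; 0.55 vs 0.40 for
  S), which also encodes the negative lignin-vs-Ac/Al association across
  the pooled plots.
* Covariates carry the reported directions: pH higher under bamboo; plant
  biomass, PLFA, CEC and Fe/Al-oxide pools higher in broadleaf; the
  ligninase/cellulase enzyme ratio lower in broadleaf; TP higher under the
  historically fertilised bamboo stands. Their absolute levels are
  plausible values for subtropical red-yellow forest soils, not
  measurements.

Within-group spreads are nowhere reported numerically, so the defaults use
a residual CV of 15% and a between-pair CV of 10%. These are assumptions;
they control power, and at n = 11 pairs the SOC contrast is borderline
(significant in some draws, not in others), which is consistent with an
effect of ~13% against a 15% CV.

What the generator does **not** emulate: spatial autocorrelation between
pairs, litter-decomposition dynamics, measurement error structure of the
chromatography, or any mechanistic link between covariates and biomarkers
beyond group-mean directions (cross-variable structure arises only through
the forest contrast and, optionally, through explicit `path_structure`
entries). Tests passing on synthetic data therefore validate the
*computational chain*, not field-scale inference.

`path_structure` deserves a note: a variable listed as a path target is
generated as a standardized linear combination of its sources plus Gaussian
noise sized (assuming independent sources) so the population standardized
coefficients equal the configured values; forest and pair effects do not
apply to such targets. This is the mechanism the path-model recovery tests
use.

## The inference chain

**Group contrasts.** `compare_groups()` is the independent two-sample
t test (pooled-variance Student by default, matching the stated analysis of
the emulated design; Welch by flag), with the percent difference of Moso
relative to broadleaf and the `*`/`**`/`ns` star convention at 0.05/0.01.
Pairing is deliberately not exploited — the emulated analysis treats plots
as independent replicates — and no multiple-testing correction is applied
across variables, again for fidelity; both choices are visible, documented
limitations. Because the shared pair effect correlates the two group means,
the independent t test is conservative on paired draws; the type-I-error
calibration in the test suite therefore runs the generator with the pair
effect and forest effect both zeroed, which is the correct null for the
test statistic itself.

**Degradation regressions.** `fit_linear()` is ordinary least squares with
a slope test, applied to total lignin against (Ac/Al)v and (Ac/Al)s.

**Variable importance.** `rf_importance()` fits a regression random forest
(1000 trees, mtry = ceiling(p/3) by default) over 13 covariates grouped as
plant biomass, soil abiotic (pH, TP, TN, DOC, CEC, clay, water content,
three Fe+Al oxide pools) and soil biotic factors (fungal and bacterial
PLFA, ligninase/cellulase ratio). Importance is out-of-bag permutation
importance expressed as percent increase in OOB MSE. Significance comes
from a response-permutation null: the forest is refitted with the response
shuffled `n_perm` times and p = (1 + #{null >= observed}) / (n_perm + 1) —
the add-one form keeps p in (0, 1] and is exact for a finite permutation
sample. Group shares floor negative importances at zero (raw values remain
in the table) and normalise to 100%. The exact group membership of the 13
predictors is configuration, not code, since reasonable groupings differ.
The published 1/82/17 and 13/80/7 percent splits for the real data are
format exemplars and cannot be reproduced without the raw plot data.

**Path model.** `fit_path_model()` estimates a recursive (acyclic) system
of standardized linear equations. Design choices, in order of consequence:

* *Composite instead of latent variable.* With n = 22 a measurement model
  for "mineral properties" is not estimable; the composite is the explicit,
  configurable recipe: first principal component of the z-scored indicators
  (`fe_al_o`, `fe_al_d`, `cec` by default; `fe_al_p` by switch),
  sign-oriented to correlate positively with an orientation variable and
  re-z-scored.
* *Estimation on the correlation matrix.* All variables are z-scored, so
  coefficients are standardized by construction and invariant to affine
  rescaling of any observed variable.
* *Closed-form ML.* For a recursive system with uncorrelated disturbances
  and a saturated exogenous block, the maximum-likelihood solution is
  equation-wise OLS. The implied covariance is
  $\Sigma = (I-B)^{-1} \Psi (I-B)^{-\top}$; the discrepancy
  $F_{ML} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$ gives
  $\chi^2 = (n-1)F_{ML}$ with df = p(p+1)/2 minus free parameters,
  $\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$, and CFI
  against the zero-covariance baseline. RMSEA is 0 and CFI is 1 whenever
  $\chi^2 \le df$; a model with every edge present is saturated and fits
  exactly. These formulas are cross-checked in the test suite against an
  independent grid-search-plus-polish minimiser of $F_{ML}$.
* *Standard errors* per edge come from the corresponding OLS equation
  (t-based); with df > 0 they are approximations to the full information
  matrix, adequate for the screening role they play here.
* A warning is emitted whenever n < 5 x free parameters — always, at the
  default design size of 22 plots with 15 free parameters, which is an
  honest statement about how fragile fit indices are at this n.

```{r sem}
fit <- suppressWarnings(fit_path_model(att, default_study_spec()))
fit
```

## Problem sizes used by the automated checks

The test suite and the acceptance script choose problem sizes once, as
package defaults for validation work: 10,000 random biomarker profiles for
the brute-force attribution oracle; 10,000 zero-effect replicates at 11
pairs for the type-I error of the t test; 100 planted-signal replicates at
n = 22 with 500 trees and 99 response permutations for the random-forest
detection check (package defaults stay at 1000 trees / 199 permutations);
n = 500 plots for the path-coefficient recovery (within ±0.1 of the
embedded −0.6 and 0.5) and for the generator-calibration checks (sample
amino-sugar ratio within two Monte-Carlo standard errors of 1.2843,
lignin ratio at least 2).

## Known limitations

* The attribution coefficients are literature conventions with substantial
  uncertainty; the package propagates them exactly and deliberately offers
  no uncertainty on the conversion itself.
* The independent t test ignores the pairing; a mixed model with a pair
  random effect would be more efficient but is out of scope by design.
* Permutation p-values below 1/(n_perm + 1) are unattainable; raise
  `n_perm` for finer resolution.
* Path-model fit indices at n = 22 are noisy; treat them as descriptive.
  The per-edge OLS standard errors ignore cross-equation covariance.
* GalN enters only the total amino-sugar pool; no GalN-specific source
  attribution is attempted.
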