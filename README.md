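# socsource

Source partitioning of soil organic carbon (SOC) from lignin-phenol and
amino-sugar biomarkers, with the full inference chain used in paired-plot
forest-conversion studies (e.g. subtropical broadleaf forest converted to
Moso bamboo plantation): biomarker → carbon-pool attribution, forest-type
contrasts, lignin degradation-index regressions, random-forest variable
importance with permutation significance, and a recursive path model with
standardized coefficients and χ²/RMSEA/CFI fit indices. A calibrated
synthetic paired-plot generator makes every stage runnable and testable
without field data.

It is written for soil biogeochemists and microbial ecologists who have a
per-plot table of CuO-oxidation lignin monomers, amino sugars, SOC and soil
covariates, and want a reproducible, scripted version of the standard
analysis instead of a spreadsheet.

## The model

Concentrations of the eight lignin monomers (grouped into vanillyl V,
syringyl S and cinnamyl C classes) and the three amino sugars (GlcN, GalN,
MurN) are in mg kg⁻¹ dry soil; pools are in g kg⁻¹:

```
plant C     = (V/0.33 + S/0.9 + C/0.03) / 1000
fungal C    = (GlcN/179.17 − 2·MurN/253.23) × 179.17 × 9 / 1000
bacterial C = MurN × 45 / 1000
microbial C = fungal C + bacterial C
```

each also reported as a percentage of SOC. (Ac/Al)v = vanillic
acid/vanillin and (Ac/Al)s = syringic acid/syringaldehyde index lignin
degradation. All constants are arguments of `attribution_coefficients()`.
See the vignette (`vignettes/soc-source-partitioning.Rmd`) for the model's
assumptions, the design of the synthetic generator, and the path-model
estimation details.

## Worked example

```r
library(socsource)

plots <- generate_paired_dataset(default_config(), seed = 42)  # 11 pairs
att   <- attribute_table(plots)
tab   <- summarize_forest_contrast(att)
tab[tab$variable %in% c("soc", "lignin_total", "plant_c", "microbial_c"),
    c("variable", "mean_broadleaf", "mean_moso", "pct_diff",
      "ratio_m_over_b", "p", "stars")]
#>      variable mean_broadleaf mean_moso pct_diff ratio_m_over_b        p stars
#>           soc          19.05     16.52    -13.2          0.868 1.88e-01    ns
#>  lignin_total         127.35    279.01    119.1          2.191 2.11e-14    **
#>       plant_c           1.51      3.36    123.2          2.232 2.81e-10    **
#>   microbial_c          10.35      7.74    -25.2          0.748 1.29e-04    **
```

On this draw the bamboo plots hold about 2.2× the lignin and plant-derived
C of the broadleaf plots, while microbial-derived C is only ~0.75× as
large — the broadleaf soil stores its (here nominally ~13% larger, at
n = 11 not significant) SOC pool mainly as microbial necromass.

```r
fit <- fit_path_model(att, default_study_spec())
fit$edges[, c("source", "target", "coefficient", "p")]
#>                     source      target coefficient        p
#>                         ph microbial_c      -0.432 0.033800
#>  ligninase_cellulase_ratio microbial_c      -0.224 0.255000
#>          mineral_composite microbial_c       0.246 0.252000
#>          mineral_composite     plant_c      -0.659 0.000856
#>                microbial_c         soc      -0.242 0.425000
#>                    plant_c         soc      -0.477 0.124000
```

Standardized path coefficients: lower pH favours microbial-derived C, and
mineral protection (Fe/Al oxides + CEC composite) suppresses plant-derived
C, as encoded in the generator. `run_pipeline(output_dir = "run1",
seed = 42)` executes the whole chain — attribution, contrasts,
regressions, importance for both carbon pools, path model — and writes the
report bundle (CSVs, `path_model.json`, `manifest.json` with the seed). A
command-line wrapper is installed at `inst/scripts/soc_pipeline.R`.

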