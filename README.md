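# protexopt

Surrogate-model optimization of an alkaline protein-extraction process.

Extraction studies in food and natural-product chemistry routinely screen a
handful of process factors — here extraction temperature (°C), time (h),
NaOH concentration (mol/L) and liquid-to-material ratio (mL/g) — with a
Box–Behnken design (BBD), fit cheap surrogate models to the measured protein
content (mg per g of powder), and optimize the surrogates instead of the
process. `protexopt` implements that workflow end to end for analysts who
want it scripted, tested and reproducible rather than locked inside
point-and-click software:

* **Design**: 4-factor BBD generation, coded/actual transforms, and the
  packaged 29-run selenium-enriched rape protein (SEP) study design with its
  measured responses (`sep_design()`).
* **Response surface**: the full quadratic model on the coded scale

  *Y* = β₀ + Σ βⱼxⱼ + Σ βⱼₖxⱼxₖ + Σ βⱼⱼxⱼ² + ε,

  fitted by OLS, with the field's standard ANOVA — partial (drop-one-term)
  sums of squares, lack-of-fit vs pure error from replicated centers, R²,
  adjusted R², PRESS-based predicted R² — plus normal residual scores and
  box-constrained surface optimization.
* **Neural surrogate**: a 4-H-1 tanh network trained by Levenberg–Marquardt
  with a seeded 70/15/15 split, validation-patience early stopping, and a
  hidden-size sweep over H = 3..12.
* **Genetic algorithm**: real-coded GA (NP = 50, Pc = 0.8, Pm = 0.2, one
  elite, 100 generations) maximizing any surrogate over the factor box.
* **Comparison**: R², RMSE, MAD (two explicit variants) and SPE, with
  optimum-condition verification arithmetic.
* **Assay arithmetic**: Bradford-type protein quantitation, extraction
  yield, DPPH/ABTS scavenging rates, CCK-8 cytostatic rate, scratch-assay
  migration rate, and amino-acid composition summaries (packaged SEP profile
  in `sep_amino_acids()`).
* **Synthetic data**: a seeded generator producing BBD datasets from a known
  quadratic plus Gaussian noise, for parameter-recovery testing
  (`simulation_spec()`, `make_study_like()`).

## Worked example

```r
library(protexopt)

design <- sep_design()          # the packaged 29-run study
fit <- fit_quadratic(design)
fit
#> Quadratic response-surface fit (coded scale), n = 29
#> (Intercept)           A           B           C           D          AB
#>     55.5840      3.5617     -0.9050     -2.3642      2.3758      1.1600
#>          AC          AD          BC          BD          CD          A2
#>      0.5875     -1.3425     -1.1550     -2.0700     -0.9450     -3.3728
#>          B2          C2          D2
#>     -2.4753     -5.0116     -5.1616
#> SSE: 23.2
```

The coded-scale coefficients read directly as effects: temperature (A,
+3.56 mg/g per coded unit) helps most, alkali (C, −2.36) hurts, and all four
quadratic terms are concave, so the surface has an interior maximum.
`rsm_anova(fit, design)` prints the full ANOVA (model F = 27.7, lack-of-fit
p = 0.155, R² = 0.965, predicted R² = 0.817): the quadratic is significant
and not lack-of-fit limited.

```r
opt <- optimize_surface(fit)
round(opt$value, 2)             # 56.94 mg/g, the box-constrained maximum
round(opt$settings, 2)          # at 64.46 degC, 2.88 h, 0.24 mol/L, 62.16 mL/g

predict(fit, c(62.5, 3.0, 0.25, 62.2))
#> 56.46  -- the model evaluated at the study's reported optimum conditions

aa <- aa_summary(sep_amino_acids())
round(c(aa$essential_pct, aa$hydrophobic_pct), 2)
#> 35.23 36.85  -- % essential and hydrophobic amino acids
```

The neural/GA arm and the side-by-side report:

```r
rep <- run_full_pipeline(design, seed = 1, outdir = "artifacts")
rep$metrics   # R2 / RMSE / MAD / SPE for RSM and ANN
rep$optima    # each model's optimum conditions and predicted mg/g
```

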