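# thymentropy

Quantifies **intra-case spatial heterogeneity** of histomorphological
features in thymectomy specimens. Standardized thymectomy work-ups yield
many slides per specimen (≈11 ± 5 tissue blocks from predefined anatomical
regions), each annotated with follicle counts, ordinal atrophy /
follicular-hyperplasia grades and estimated fat percentages. Location
parameters (mean, median, mode) capture how much of a feature a specimen
has; this package captures how *unevenly* it is distributed across the
specimen, producing one heterogeneity value per case and feature that can
enter ordinary clinico-pathological statistics.

It is intended for pathologists and biostatisticians working with
multi-slide (multi-region) measurements per specimen — thymus here, but any
"one value per slide, many slides per case" design fits the data model.

## The statistic

Raw slide values are discretized into integer levels (grades 0–4 stay as-is;
follicle counts get 10 levels of width 5 over 0–50; percentages 10 levels of
width 10%). For a case with *m* measurement points, with *p*ᵢ the empirical
relative frequency of the level observed at point *i*, the per-case entropy
is the per-point sum

&nbsp;&nbsp;&nbsp;&nbsp;*H* = −Σᵢ₌₁..ₘ *p*ᵢ log₂ *p*ᵢ  [bit],

which is 0 exactly when every slide shows the same level and has the
theoretical ceiling *H*ₘₐₓ(*m*, *L*) = *m*·(1/*L*)·log₂ *L* for an *L*-level
variable (e.g. 2.786 bit for 6 slides of a 5-grade variable, 1.993 bit for
6 slides of a 10-level variable). The classical per-level Shannon entropy
−Σₖ *p*ₖ log₂ *p*ₖ is reported alongside, and a rarefied (depth-corrected)
variant backs the sampling-depth diagnostic. Downstream the package provides
the conventional clinical statistics: Shapiro-gated t/Wilcoxon group tests,
Pearson correlations, an explorative linear/logistic model grid of six
clinical endpoints on the four entropy features, single-predictor refits,
and seeded k-fold cross-validation — plus a synthetic cohort generator with
plantable effects for validation.

## Worked example

A built-in two-case demonstration table exercises every level boundary:

```r
library(thymentropy)
prof <- compute_entropy_profiles(demo_slide_table())
subset(prof, case_id == "DEMO_HET")
#>  case_id                variable staining m H_point H_shannon H_max
#> DEMO_HET              n_follicle     CD23 6   2.585     2.585 1.993
#> DEMO_HET        grading_follicle     CD23 6   2.780     2.252 2.786
#> DEMO_HET grading_intrathymic_fat       HE 6   2.780     2.252 1.993
#> DEMO_HET         grading_atrophy       HE 6   2.780     2.252 2.786
```

Six all-distinct follicle levels give log₂ 6 = 2.585 bit; the homogeneous
companion case `DEMO_HOM` scores 0 everywhere. A full simulated run — here
200 cases with the generator's default planted effect (0.8 g/bit of
intrathymic-fat entropy on post-operative prednisone load):

```r
cfg <- cohort_config(n_cases = 200, seed = 42)
res <- run_pipeline("cohort_out", simulate = cfg, seed = 42)
res$model_grid
#> Explorative model grid (cells: p-values, * < 0.05):
#>                    (Intercept) n_follicle grading_follicle grading_intrathymic_fat grading_atrophy   family
#> qmg_drop_m12_36        0.000 *      0.113            0.208                   0.456           0.640 logistic
#> mms_m12_36               0.053      0.868            0.539                   0.143           0.494 logistic
#> qmg_baseline           0.000 *      0.637            0.260                   0.584         0.039 *   linear
#> mg_duration_months     0.000 *      0.314            0.301                   0.429           0.598   linear
#> prednisone_pre_g       0.000 *      0.991            0.195                   0.148           0.340   linear
#> prednisone_post_g      0.000 *      0.990            0.797                 0.000 *           0.465   linear
res$cv
#> 3-fold CV (seed 42, n 200): mean held-out MSE 84.91 +- 9.56; full-data MSE 82.76
```

The planted fat-entropy cell is the strong hit (its single-predictor refit:
slope 0.96 ± 0.26 g/bit, p = 2.4e-04, R² = 0.066); the `qmg_baseline ×
grading_atrophy` star is the kind of single false positive an uncorrected
24-cell explorative grid is expected to produce. Held-out MSE close to the
full-data MSE indicates no overfitting. `run_pipeline()` writes the full
report bundle (entropy table, feature-correlation matrix, model grid CSV +
JSON, single-predictor refits, CV report, run log) into the output
directory; `entropy_sample_size_check()` verifies that per-case entropy does
not merely track the number of slides.

## Layout

- `R/` — data model & I/O, level schemes, entropy statistics, statistical
  layer, cohort generator, pipeline.
- `vignettes/entropy-heterogeneity.Rmd` — methods: model, assumptions,
  parameter choices, generator design, limitations.
- `inst/cli/thymentropy.R` — thin command-line front-end
  (`run` / `simulate` / `entropy`).
- `tests/testthat/` — unit, property and acceptance suites.
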