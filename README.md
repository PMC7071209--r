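# ppgr

Predicting postprandial glycemic responses (PPGR) in pregnant women — with
and without gestational diabetes mellitus (GDM) — from meal composition,
glycemic index/load, continuous glucose monitoring (CGM), and patient
characteristics.

The package is a complete, tested implementation of a free-living PPGR
study pipeline:

1. **Food library.** A five-rule glycemic index (GI) assignment hierarchy
   (published GI → GI 0 below 5 g carbohydrate/100 g → close match →
   subgroup mean → expert default), and mixed-meal arithmetic

   $$gi_{meal} = \frac{\sum_i gi_i \, carbo_i}{\sum_i carbo_i},\qquad
     gl = \frac{1}{100}\sum_i gi_i \, carbo_i,$$

   where $carbo_i$ is the grams of carbohydrate contributed by item $i$,
   so $gl = gi_{meal}\cdot carbo/100$ holds exactly.
2. **CGM ↔ diary linkage.** Paper-protocol meal starts are matched to the
   nearest electronic-diary meal (greedy, 60-min cap), then four timing
   rules exclude meals whose reported start is implausible against the
   glucose trace: *late report* (BG at start > 1.0 mmol/L above one hour
   earlier), *falling edge* (±0.5 mmol/L half-hour ladder), and *prior* /
   *subsequent* meals within 60 min.
3. **Outcomes.** From each kept meal: BG0, BG60, BGMax (3-h window),
   BGRise, AUC60/120 and incremental iAUC60/120 (positive increments above
   the BG0 baseline, exact crossing insertion), in mmol/L·h.
4. **Filters.** Patient-level misreporting (all-single-item diaries; > 5
   fully 100 g-rounded meals) and record filters (undefined GI; mean
   incremental response below 0.3 mmol/L/h despite > 40 g carbohydrate).
5. **Models.** Forward stepwise regression on all records, and a
   regularized track — Spearman prefilter (|r| > 0.1), mean/l2-norm column
   normalization, then OMP, LARS lasso, lasso, ridge, or elastic net with
   patient-grouped 70/30 splitting, grouped 10-fold cross-validated grid
   search, optional degree-2 polynomial meal features, and a with/without
   GI/GL arm comparison scored by Pearson R and MAE on held-out patients.
6. **Synthetic cohort generator.** Every input (CGM traces, diaries,
   protocols, food table, patient profiles) with a planted linear iAUC120
   signal, injected reporting errors, and a closed-form performance
   ceiling (`theoretical_r`), so the whole pipeline is testable against
   known ground truth.

OMP and the LARS-lasso path algorithm are implemented in the package;
lasso/ridge/elastic-net solutions go through glmnet.

## Worked example

```r
library(ppgr)

cfg    <- generator_config(seed = 42)   # the default synthetic study
cohort <- gen_cohort(cfg)
res    <- process_cohort(cohort, pipeline_config(input_dir = ".", out_dir = "."))
res$counts
#> protocol_entries  unmatched  matched  late_report  falling_edge  prior_meal
#>             1490         38     1452           94            11          15
#> subsequent_meal  cgm_unavailable  kept_after_exclusion  misreporter_patients
#>              47                0                  1285                     4
#> misreporter_records  cgm_incomplete_records  gi_undefined  small_ppgr  final_records
#>                  90                       0             3          22           1170

res$design
#> <ppgr_design> 1170 meals, 56 patients, 87 features, arm: with_gigl

split <- grouped_split(res$design, fraction = 0.7, seed = 42)
model <- fit_regularized(split$train, "iauc120", method = "lars_lasso",
                         k = 10, seed = 42)
round(coef(model), 3)
#>             gl          carbo          water            bg0 bread_before_1
#>          3.784          8.921          0.167         -4.399          1.904

evaluate(model, split$test)
#>   outcome       arm     method pearson_r   mae    r2 n_test n_coefficients frac_large_error
#> 1 iauc120 with_gigl lars_lasso     0.677 0.557 0.424    356              5            0.149

theoretical_r(cfg)
#> [1] 0.604
```

Reading the output: of 1490 protocol entries, 1452 matched a diary meal;
the four timing rules and the misreporting/record filters leave 1170 meals
from 56 patients. On held-out patients the cross-validated LARS-lasso
model selects the planted predictors (carbohydrate, glycemic load, pre-meal
glucose — signs as planted; coefficients are on normalized columns) and
reaches Pearson R = 0.68 against a generative ceiling of 0.60 for this
cohort draw; 15% of test meals have an absolute iAUC120 error above
1.0 mmol/L·h.

`run_comparison()` produces the full outcome × arm × method tables, and
`run_pipeline()` runs the same chain as file-based stages
(`simulate`, `ingest`, `match`, `ppgr`, `features`, `fit`, `report`) with
CSV artifacts and a run log; `inst/scripts/ppgr-pipeline.R` is a thin
command-line wrapper over it.

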