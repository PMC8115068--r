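# fdopa

Striatal [18F]FDOPA PET indexes presynaptic dopamine synthesis capacity and
separates patients with psychosis who respond to first-line antipsychotics
from those who need clozapine.  Turning that observation into a usable
stratification biomarker raises a chain of methodological questions: how to
quantify uptake (full dynamic Patlak vs. a short static SUVR scan), how
reliable the measures are test-retest, how well they discriminate
non-responders — especially at the clinically critical 100%-specificity
operating point, where nobody is sent to clozapine by mistake — whether
voxel-wise machine learning beats region averages, and whether scanning a
whole first-episode cohort would pay for itself.

`fdopa` implements that entire evaluation chain as a tested R package
operating on **synthetic dynamic PET cohorts with known ground truth** (the
clinical datasets the design mirrors are not publicly deposited).  It is
aimed at imaging methodologists who want to stress-test the pipeline's
statistical machinery, and at anyone who needs a reference implementation
of its components.

## What is inside

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `cohort_design()`, `simulate_cohort()`, `simulate_test_retest()`, `make_reference_tac()`, `make_tissue_tac()`, `make_striatal_mask()` |
| Kinetic quantification | `patlak_transform()`, `fit_patlak()`, `roi_ki()`, `parametric_map()` |
| Simplified protocol | `static_frame()`, `compute_suvrc()`, `compute_snr()` |
| Reliability | `percent_var()`, `icc_two_way()`, `gated_correlation()` |
| Discrimination | `cohens_d()`, `roc_curve()`, `sensitivity_at_full_specificity()` |
| Voxel-wise ML | `extract_feature_matrix()`, `model_spec()`, `loocv_evaluate()`, `combine_cohorts()` |
| Health economics | `econ_scenario()`, `econ_outcome()`, `breakeven_sensitivity()`, `savings_surface()` |
| I/O & pipeline | NIfTI-1 read/write, `read_dynamic_scan()`, `run_config()`, `run_pipeline()` |

The core quantity is the reference-region Patlak influx constant: after
equilibration, \(C_T(t)/C_R(t) = K_i^{cer} \int_0^t C_R\,d\tau / C_R(t) + v'\),
fitted by (optionally duration-weighted) least squares from a configurable
\(t^*\) (default 30 min).  SUVR is the striatum/cerebellum activity ratio in
an explicit late window.  See `vignette("fdopa-methods")` for every
modelling decision and its rationale.

## Worked example

```r
library(fdopa)

design <- cohort_design(n_responder = 13, n_nonresponder = 13)
cohort <- simulate_cohort(design, seed = 1)

# dynamic quantification of one subject, against its ground truth
roi_ki(cohort[[20]], "associative")
#> <patlak_fit> ki_cer = 0.01335 /min, intercept = 0.439 (t* = 30 min, n = 13, R2 = 0.955)
cohort[[20]]$truth_roi$ki_associative
#> 0.01257

# responder / non-responder discrimination on whole-striatum Ki
ki  <- sapply(cohort, function(s) roi_ki(s, "striatum")$ki_cer)
grp <- sapply(cohort, `[[`, "group")
pat <- grp != "control"
rc <- roc_curve(labelled_scores(ki[pat], grp[pat] == "nonresponder",
                                positive_low = TRUE))
rc
#> <roc_result> AUC = 0.888 (p = 0.000384), sens@100%spec = 46.2% [low-positive, 13 pos / 13 neg]

cohens_d(ki[grp == "responder"], ki[grp == "nonresponder"])$cohens_d
#> 1.67

# economics at the zero-false-positive operating point just measured
econ_outcome(econ_scenario(sensitivity = rc$sens_at_full_spec, specificity = 1))
#> <econ_outcome> net +2782 GBP/patient (benefit 7327523, cost 4545923; TP 152.3 FP 0.0)
breakeven_sensitivity(econ_scenario())   # at the default 95% specificity
#> 0.267
```

Reading the numbers: the Patlak fit recovers this subject's generating
associative-striatum Ki (0.01335 vs. 0.01257 min⁻¹, ~6% off at the default
noise level); across the 26 patients the whole-striatum Ki separates groups
with AUC 0.89 and identifies 46% of non-responders with zero false
positives; feeding that sensitivity into the screening model yields a net
saving of ~£2800 per screened patient, and the default scenario breaks even
once sensitivity exceeds ~27%.  Exact values depend on the simulation seed.

The full pipeline (simulate → Patlak → SUVR → reliability → correlations →
effect sizes → ROC → voxel classifiers → economics) runs from one seed:

```r
report <- run_pipeline(run_config(seed = 42), "my_run")   # writes CSVs
```

or from the command line:

```sh
Rscript $(R -e 'cat(system.file("cli","fdopa.R",package="fdopa"))') run --seed 42 --out-dir my_run
```

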