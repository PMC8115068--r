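---
title: "Models and methods behind the fdopa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fdopa package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdopa)
```

## What the package models

Striatal [18F]FDOPA PET measures presynaptic dopamine synthesis capacity.
With a dynamic (~90-95 min) acquisition and a cerebellar reference region
(negligible specific dopamine synthesis), the influx constant
$K_i^{cer}$ (min$^{-1}$) is obtained from the reference-input Patlak-Gjedde
plot: for an irreversibly trapped tracer,

$$\frac{C_T(t)}{C_R(t)} \;=\; K_i \,
  \frac{\int_0^t C_R(\tau)\,d\tau}{C_R(t)} \;+\; v'$$

becomes linear in the "normalised time" abscissa once the free compartments
have equilibrated; the slope is $K_i$ and the intercept $v'$ an effective
distribution volume.  A simplified protocol replaces the dynamic scan with a
short late static frame and the ratio of striatal to cerebellar activity
(SUVR).  The package evaluates the whole biomarker chain - quantification,
test-retest reliability, responder/non-responder discrimination, voxel-wise
classification, and screening economics - on *synthetic* cohorts with known
ground truth, because the clinical datasets this design mirrors are not
publicly deposited.  Every downstream claim is therefore a property of the
method, never a reproduction of clinical values.

## The synthetic world

`cohort_design()` fixes the generating distribution; its defaults are the
package's "stated world" and are deliberately not tuned against any test
outcome:

* **Group sizes** 13/13/13 (controls/responders/non-responders) and a
  test-retest arm of 8 subjects, mirroring typical single-site psychosis
  PET cohorts.
* **Kinetics.**  Control/responder mean $K_i$ per striatal subdivision
  ~0.0125-0.014 min$^{-1}$ with 10% between-subject SD - the magnitude
  range conventional for FDOPA - and a shared Patlak intercept $v' = 0.5$.
  Non-responders are shifted down by `cohens_d * between_subject_sd`
  (defaults 0.8/1.1/0.6 for limbic/associative/sensorimotor), placing the
  largest separation in the associative subdivision, the region where
  dopaminergic alterations in psychosis are most marked.  A subject factor
  with correlation 0.7 across subdivisions reflects that striatal
  subdivisions covary within subject.
* **Reference curve.**  A gamma-variate with a slow washout tail
  (`make_reference_tac()`), peaking ~5 min, evaluated on a 1 s grid and
  averaged within frames.  The family is a generator convenience only; no
  estimator assumes it.
* **Noise.**  Multiplicative Gaussian frame noise with variance inversely
  proportional to frame duration, calibrated so the longest (300 s) frames
  sit at the configured CV.  Two components: a per-region shared component
  at the design's ROI-level CV (default 5%) and an independent per-voxel
  component (default 15%).  The split is what makes both ROI statistics and
  voxel-map/SNR behaviour realistic at the same time: purely independent
  voxel noise would average away to implausibly quiet ROI curves, while
  purely shared noise would give noiseless-looking parametric maps.
  Radioactive decay is not modelled (all activities are decay-corrected by
  convention), and there is no scanner PSF, attenuation, scatter or motion.
* **Voxel heterogeneity.**  Within a subdivision, voxel $K_i$ = subdivision
  $K_i \times (1 + \epsilon)$ with 5% jitter.
* **Masks.**  `make_striatal_mask()` builds a schematic box geometry with
  exactly 2847 striatal voxels (15% limbic, 55% associative, 30%
  sensorimotor), a cerebellar block and an extra-striatal brain block with
  zero influx.  Only the label bookkeeping and feature dimensionality are
  meaningful; there is no anatomical realism.

A green test on this world establishes that the estimators recover what the
generator put in, at realistic noise; it does not establish clinical
performance, scanner robustness, or anatomical validity.

## Discretisation: why generator and estimator share one rule

The Patlak estimator works on frame-binned data: frame midpoints as time
points and a cumulative trapezoid from $(t, C_R) = (0, 0)$.  The tissue
generator composes $C_T = K_i \int C_R + v' C_R$ with *the same* midpoint
trapezoid on the frame-binned reference rather than integrating on the fine
grid and binning afterwards.  The two orders of operation differ at the
order of the discretisation error; only the shared rule makes noiseless
generation exactly invertible (recovery to machine precision for any
$t^*$), which in turn makes "estimator exactness" a sharp, testable
property instead of a tolerance judgement.  The reference curve itself is
still produced by fine-grid evaluation and frame averaging.

`t*` defaults to 30 min.  The source protocols note Patlak linearity in the
60-90 min window but never state their $t^*$; 30 min is the conventional
FDOPA choice, it is configurable, and it is recorded in every output.
Uniform least squares is the default; frame-duration weighting is available
because late 300 s frames are less noisy than early 15 s frames.

Parametric maps use an independent per-voxel ordinary least-squares Patlak
fit (all voxels share the reference abscissa, so the fits vectorise into
one matrix operation), with optional Gaussian pre-smoothing, off by
default.  This is a deliberate, documented substitution for the wavelet
parametric-imaging method used with the original data, which is out of
scope here.

## SUVR windows

"SUVR at 60/75/90 min" is interpreted as the window *start* time, with the
window length an explicit, never-defaulted-silently parameter (the source
material alternates between 10 and 15 min windows).  Frames partially
covered by a window contribute by overlap fraction.  A consequence of the
start-time reading: a 10-min window at 90 min does not fit inside a 95-min
acquisition, so the pipeline drops (with a message) any configured window
that would run past the end of the scan rather than silently truncating
it.  The static-image SNR is the striatal mean over the SD of extra-striatal
brain signal; on a noiseless image that SD is zero and the function refuses
to divide, by design.

## Reliability statistics

%VAR is the exact printed formula
$2\,|retest - test|/(test + retest) \times 100$.  The two-way ICC is
computed from the ANOVA mean squares of the subjects-by-sessions layout.
Because the convention ("two-way random" with "fixed session effects") is
ambiguous between consistency and absolute agreement, both single-measure
forms are always reported with explicit tags: ICC(3,1) consistency as the
primary (sessions fixed) and ICC(2,1) absolute agreement alongside.  A
constant session offset lowers only the agreement form - the package treats
that divergence as information, not as a choice to hide.

Correlations between SUVR and $K_i$ are gated per variable by Shapiro-Wilk
at $\alpha = 0.05$: Pearson when both variables pass, Spearman otherwise,
with the chosen method recorded.

## Discrimination

Non-responders form the positive class and are expected *lower* on
$K_i$/SUVR; `roc_curve()` auto-orients (logged) unless the orientation is
fixed.  AUC is the trapezoid over the empirical curve - identical to the
Mann-Whitney statistic with half-credit ties - and its p-value against 0.5
comes from the Wilcoxon rank-sum equivalence.  Sensitivity at 100%
specificity counts only non-responders *strictly* beyond the most extreme
responder value: ties are not detections, guaranteeing literally zero false
positives at the reported operating point.

## Voxel-wise classification

Features are the 2847 striatal voxel $K_i$ values, raw, flattened in fixed
mask order; labels are +1 (non-responder) / -1 (responder).  The zoo
matches the evaluated families: ridge-penalised Bernoulli logistic and
linear SVM (linear models $f_i = W x_i + b$ minimising
$\sum_i l(y_i, f_i) + \alpha\|W\|^2$, $\alpha = 1$; the penalised-objective
sign convention is used), an RBF SVM, a 100-tree random forest, kNN with 2
or 3 neighbours, and a squared-exponential Gaussian-process classifier with
probit link fitted by Laplace approximation.  Because no SVM/forest/GP
implementation ships with the runtime environment, these learners are
implemented in-package: the kernel machines in the dual (exact when
subjects $\ll$ voxels), the forest as a compact CART ensemble.  The RBF/GP
squared lengthscale defaults to (number of voxels) $\times$ (mean feature
variance); the forest uses $\sqrt{V}$ features per split; kNN scores by the
positive fraction among neighbours.

**How LOO outputs become an AUC** was genuinely open, and the obvious
answer is wrong in an instructive way.  Pooling the N raw leave-one-out
decision scores into one ROC is sharply anti-biased: each fold's training
set under-represents the held-out subject's class, so under a label
permutation the pooled AUC concentrates *below* 0.5 (it can reach exactly 0
on strongly clustered data).  Per-fold centring on the training-score mean
removes the first-order intercept artefact but not the residual, which we
measured at ~0.35 under permutation on a strongly separated cohort.  The
package therefore defaults to the leave-pair-out estimator: every
(non-responder, responder) pair is held out together, the model is fitted
on the remaining N-2, and AUC is the concordant fraction - the standard
nearly unbiased choice for exactly this situation (measured permutation
null ~0.47-0.49 here).  The pooled-LOO variant remains available as
`auc_method = "pooled"` for comparison, and both honour the invariant that
a held-out subject's label can never influence its own score (the package
even avoids warm-starting fold optimisations from the all-subject fit so
the independence is structural, not just approximate).  Stochastic
families report mean and SD over 100 seeds by default; deterministic
families are seed-invariant.

## Health economics

The screening model is an explicit closed form over a cohort of $N$
patients, prevalence $p$ of non-response, operating point $(se, sp)$:
$TP = p\,se\,N$, $FP = (1-p)(1-sp)N$,

$$\text{net/patient} = \frac{TP \cdot r \cdot s \cdot d
  - \big[N c_{scan} + (TP{+}FP)(c_{cloz} d + i_{neu} c_{neu})
  + FP \cdot c_{fp}\big]}{N}$$

with $r$ the clozapine response probability, $s$ the annual saving of
moving a patient from active psychosis to remission, $d$ the years of
clozapine delay avoided.  Published assumptions fix $c_{scan}$ = £3000,
$p$ = 0.33, $s$ = £39,141 - £15,086 = £24,055 (the exact difference is the
default; the rounded ~£24,000 can be passed explicitly), $d$ = 4, $r$ =
0.5 and a 3% neutropenia incidence.  Clozapine annual cost, neutropenia
management cost and any false-positive penalty have **no published
values**; the constructor carries illustrative defaults (£2500/yr, £5000,
£0) so a default scenario exists, and the CLI config template flags them
for review.  The model is affine in sensitivity and in $(1-sp)$, so the
bisection breakeven (tolerance 1e-6) coincides with the closed-form root -
both are tested.  The published headline outputs (~£3400/patient,
26% breakeven) rest on unpublished model structure and are deliberately
not asserted; the parameter space here can express them but the package
makes no claim to reproduce them.

## Numerical and degenerate-input choices

* Patlak fitting requires ≥ 3 usable points after $t^*$ and errors
  otherwise; zero/negative reference activity after the first frame names
  the offending frame.
* `percent_var` refuses non-positive test+retest sums; `icc_two_way`
  refuses zero total variance; `compute_snr` refuses zero extra-striatal
  SD; constant inputs to `gated_correlation` are errors, not NA.
* Single-valued score vectors yield AUC 0.5 with a warning.
* Noise never drives activity negative (clipped at zero); with the default
  CVs clipping is an extreme-tail event with negligible effect on
  calibration.
* All randomness flows through explicit seeds; the pipeline derives stage
  seeds from one master seed and its CSV outputs are byte-identical across
  reruns.

## Known limitations

Schematic masks and box geometry; no arterial-input modelling, no
reversible-tracer extensions, no attenuation/motion/PSF simulation; the
forest/GP learners are compact reference implementations, not
performance-tuned libraries; and the economic model is illustrative - its
unpublished-parameter defaults shift the breakeven point materially and
must be localised before any real-world use.
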