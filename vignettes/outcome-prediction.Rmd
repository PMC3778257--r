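---
title: "Predicting surgical seizure outcome from white-matter morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting surgical seizure outcome from white-matter morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

About a third of patients with mesial temporal lobe epilepsy (mTLE) who
undergo selective amygdalohippocampectomy are not freed from their
seizures, and pre-surgical diagnostics offer no solid criterion to predict
who will benefit. `wmpredict` implements a multivariate pattern analysis
that addresses this at the level of the individual patient: each subject's
smoothed white-matter (WM) tissue-probability volume is treated as a single
point in a voxel space, and a linear soft-margin support vector machine
(SVM) is trained to separate patients with a favorable outcome (ILAE
classes 1–2, labeled $+1$) from those with a non-favorable outcome (ILAE
3–6, labeled $-1$).

```{r setup}
library(wmpredict)
```

## The procedure

The pipeline has four stages.

**1. Volumes to features.** Subject volumes (values in $[0,1]$, tissue
probabilities) are smoothed with an isotropic-in-mm Gaussian kernel
(default FWHM 3 mm; per-axis $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$
voxels, truncated at $4\sigma$ and renormalized per output voxel so a
constant volume is preserved exactly at the edges). Voxels whose
cohort-mean intensity exceeds a threshold (default 0.05) form the analysis
mask — a configurable stand-in for an anatomical WM mask, which excludes
empty background. `build_dataset()` flattens the in-mask voxels into the
$N \times n$ matrix `X` and keeps an invertible column-to-voxel map.

**2. Fisher-criterion voxel ranking.** Each voxel $v$ is scored by

$$ f_v = \frac{(\hat\mu_{+} - \hat\mu_{-})^2}{\hat\sigma_{+} + \hat\sigma_{-}}, $$

the squared class-mean distance over the *sum of the intra-class standard
deviations*. Two points deserve emphasis. First, the denominator is the sum
of standard deviations — not the conventional Fisher ratio with summed
variances; the conventional form is available via
`fisher_scores(..., denominator = "variance")`, and since the score is used
only for ranking the two rarely disagree on order. Second, standard
deviations are population-flavored (divide by class size) by default, with
`sd_type = "sample"` available; again only the ranking matters. Voxels with
zero denominator score 0 when the class means agree and otherwise inherit
the maximum finite score, so a perfectly separating constant voxel ranks
first and the ranking stays total. Ties in `rank_and_select()` break toward
the smaller column index, making selection fully deterministic.

**3. Nested leave-one-subject-out cross-validation.** The outer loop leaves
each subject out once. On the remaining $N-1$ subjects an inner LOSO loop
evaluates every cell of a hyperparameter grid — regularization constants
$C$ and voxel counts $k$ — where each inner fold recomputes Fisher scores
on its own $N-2$ subjects before selecting the top $k$. The cell with the
best inner (sample) balanced accuracy wins; ties break toward smaller $k$,
then smaller $C$, preferring the sparser and smoother model. The winning
$(C^\*, k^\*)$ is then re-derived on all $N-1$ training subjects and the
held-out subject receives one out-of-fold decision value
$f(x) = w \cdot x + b$. Feature selection and model selection therefore
never see the test subject; the suite asserts this *leakage invariant*
exactly, by replacing a held-out subject's feature row with junk and
checking that its fold's hyperparameters and selected voxels are unchanged.
Inner folds whose training remainder lacks two subjects of either class are
skipped and the inner balanced accuracy is renormalized over the evaluated
folds — unavoidable at $N-2$ with small minority classes.

The default grid is the usual log-spaced libsvm convention
$C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$ with
$k \in \{10, 20, 50, 100, 200, 310, 360, 500\}$. The original study never
published its grids; 310 and 360 are included because they are the voxel
counts its two cohort models ended up using. Grid $k$ values exceeding the
mask size are dropped from the search.

**4. Evaluation and interpretation.** Out-of-fold decisions are
thresholded at zero — strictly positive predicts favorable, and an exact
zero maps to non-favorable, the conservative clinical direction — into a
confusion matrix with sensitivity, specificity, balanced accuracy, PPV,
positive likelihood ratio and F-measure. The SVM solves the standard
soft-margin problem (libsvm backend through e1071, termination tolerance
$10^{-7}$); the suite checks the KKT conditions, the representation
identity $w = \sum_i \alpha_i y_i x_i$, and agreement of the optimizer's
objective with an exhaustive active-set QP oracle on small instances. No
feature standardization is applied before the SVM: WM intensities already
share the $[0,1]$ scale (configurable).

### Balanced posterior accuracy

The headline balanced accuracy is the *sample* value
$(\mathrm{sens} + \mathrm{spec})/2$. Its uncertainty statement places
independent uniform-prior beta posteriors on the two rates,
$\mathrm{Sens} \sim \mathrm{Beta}(TP+1, FN+1)$ and
$\mathrm{Spec} \sim \mathrm{Beta}(TN+1, FP+1)$, and reports a central
credible interval of $B = (\mathrm{Sens} + \mathrm{Spec})/2$ from
Monte-Carlo draws (default $10^6$, seeded). The split matters: the
posterior mean of $B$ is pulled toward $1/2$ by the priors (about 86% and
90% for the two shipped cohorts) and is *not* the headline number (94% and
96%). Simulated at true rates $(0.9, 0.8)$ with $n = (11, 8)$ the nominal
95% interval covers the true balanced accuracy 0.85 with probability
0.939 (computed by exact enumeration of all confusion outcomes), so the
interval is mildly conservative-leaning but close to nominal.

The AUC is computed by exhaustive pair counting (ties one half), which
equals the trapezoidal area under the empirical ROC. For the shipped
per-patient decision values this gives 0.943 (men) and 0.981 (women);
note these are properties of the printed decision values under the
rank-based definition and are reported as such.

### Discrimination maps and lateralization

The linear kernel permits back-projection: `weights_to_volume()` renders
$w$ at its voxel coordinates (zero elsewhere). Whether such a map should
come from one refit on all subjects or from averaging the per-fold models
is genuinely open; `final_model()` implements the refit reading (grid
search over all $N$, then one fit), and `fold_average_map()` provides the
fold-averaged alternative, tagged in the map's provenance field.

`lateralization_summary()` splits the non-zero voxels by hemisphere and by
weight sign and tests each contrast against a uniform 50/50 expectation
with a df-1 chi-square goodness-of-fit test, no continuity correction.
Whether the "weighting distribution" should count voxels or sum weight
magnitude is not decidable from the source; counts are the default (the
natural $\chi^2$ object) and `unit = "weight"` applies the same statistic
to summed $|w|$, with the choice recorded in the output. The first grid
axis is the left–right axis and 1-based indices at or below
$\lfloor d_1/2 \rfloor$ are LEFT — an arbitrary but fixed convention shared
with the synthetic generator. All voxel coordinates in this package are
1-based, the R convention.

### Clinical statistics

The cohort-comparison layer wraps the standard tests: Fisher's exact 2×2
(two-sided by the minimum-likelihood rule, the convention of base R's
`fisher.test`), Mann–Whitney U from midranks (exact distribution when
untied and the smaller group has ≤ 12 observations, otherwise normal
approximation with tie and continuity correction; the backend used is
reported), tie-corrected Kruskal–Wallis, and Spearman rank correlation
with a tie-safe t-approximation p. "Support-vector weighting" per subject
is read as the magnitude of the out-of-fold decision value — the only
printed per-subject quantity; partitioning by the dual coefficient
($\alpha > 0$) is what `sv_vs_nonsv_comparison()` uses to cross support
status with outcome group. With every subject (or none) a support vector
the SV contrast is degenerate and flagged as such, while the outcome split
is still reported.

## The synthetic cohort generator

Real patient volumes are not distributable, so the generator is a
first-class module. Each subject is `baseline` plus, inside each planted
spherical effect, $\pm\delta/2$ by class, plus independent per-voxel
Gaussian noise; the sum is smoothed and clipped to $[0,1]$. Noise is added
*before* smoothing so the output carries the spatial correlation of real
smoothed VBM segments. In expectation the class means differ by $\delta$
inside each effect and nowhere else. Clinical covariates are only
marginally plausible — discrete-uniform ages, Bernoulli febrile history,
log-normal seizure frequencies, follow-up floored at 12 months (the
one-year outcome-rating inclusion criterion) — with location parameters
steerable toward the published cohort medians.

Default conditions: $16^3$ grid at 1 mm voxels, 10 + 10 subjects, baseline
0.5, `noise_sd` 0.05, FWHM 3 mm. The study the package reimplements
reports no WM effect size between outcome groups, so $\delta$ is a
calibration choice, not an estimate: the "strong signal" condition used in
tests plants one right-hemisphere sphere (radius 3) with
$\delta = 3 \cdot \texttt{noise\_sd} = 0.15$.

What the generator does *not* emulate: brain anatomy, registration error,
modulation, scanner effects, or realistic inter-subject anatomical
variance (its only between-subject variation is noise). Passing tests
therefore demonstrate the correctness and leakage-freeness of the
machinery, not expected accuracy on real MRI.

## Simulation design of the test suite

The suite's problem sizes are the package's own choices, balancing the
properties being demonstrated: oracle checks for the SVM use ≤ 6-point
instances (exhaustive active-set enumeration is exact there); smoothing is
verified against a dense-convolution oracle on $9^3$ grids; the
chance-calibration study runs 20 null cohorts (no planted effect) at the
generator defaults with grid $C \in 2^{\{-5,-1,3,7,11,15\}}$,
$k \in \{10, 50\}$, giving mean out-of-fold balanced accuracy 0.46;
strong-signal runs use the $\delta = 3\sigma_{\text{noise}}$ condition
above; interval coverage uses 1000 simulated confusion matrices.

One behavior uncovered by these simulations deserves a warning. Honest
LOSO with training-set feature selection is *pessimistically* biased on
null data at small $N$: in exploratory runs with 6 + 6 subjects the mean
null balanced accuracy fell to ~0.33, and with aggressive selection and a
single small $C$ the classifier degenerates to a majority vote over the
training fold — which is always the opposite of the held-out subject's
class, driving balanced accuracy toward zero. This below-chance
phenomenon is well documented for cross-validated classification tests at
small samples; it disappears in expectation as $N$ grows (at the default
10 + 10 the null calibration is within [0.40, 0.60]) but means a single
below-chance run on a small cohort is *not* evidence of an
implementation error.

## Worked example

```{r example, eval = FALSE}
eff <- planted_effect(center = c(12, 8, 8), radius = 3,
                      hemisphere = "right", delta = 0.15)
spec <- cohort_spec(effects = list(eff), seed = 42)
coh <- generate_cohort(spec)
res <- run_pipeline(coh, hyper_grid(C_values = c(0.1, 1, 10),
                                    k_values = c(10L, 30L)))
res$evaluation$confusion
res$lateralization$tests
```

On this planted-effect cohort the nested CV recovers every subject's label
out of fold and the recovered discrimination map is entirely
right-lateralized — the left-vs-right chi-square rejects at p < 0.002 with
the 10 selected voxels (a 10-voxel map caps the statistic at 10; more
selected voxels sharpen it).

## Published-results fixtures

The per-patient prediction tables of the two original cohorts (19 men, 30
women) are printed in full in the source publication's supplement and ship
as plain-CSV fixtures, along with the individual clinical characteristics.
They exercise the evaluation layer against known numbers:
`confusion_from_decisions()` on the male fixture yields TP 11, FN 0, TN 7,
FP 1 — sensitivity 100%, specificity 88%, balanced accuracy 94%, PPV 92%,
likelihood ratio 8, F-measure 0.96 — and the beta-posterior interval
rounds to [70%, 97%]. One fixture subtlety: female patient F19's printed
prediction-table label contradicts her ILAE class 3 clinical record; the
fixture carries the clinically consistent non-favorable label (making her
decision value a true negative) and preserves the printed value in
`actual_printed`.

## Known limitations

- The original study's hyperparameter grids, software versions and exact
  ROC construction are unpublished; the printed AUCs (0.93/0.95) do not
  equal the rank-based AUC of the printed decision values and are not
  targeted.
- The female febrile-seizure Fisher p printed as 0.71 is not reproduced by
  the minimum-likelihood convention (which gives 1.0 for those margins);
  only the male value is checked.
- Whether the published lateralization chi-squares counted voxels, weight
  mass or clusters is unstated; both count- and weight-based tests are
  provided but no published p-value is targeted.
- Anatomical labeling of discriminative clusters requires an atlas and real
  anatomy and is out of scope.
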