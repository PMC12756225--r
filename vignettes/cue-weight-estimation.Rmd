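---
title: "Estimating depth-cue weights with the constrained vector-sum model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating depth-cue weights with the constrained vector-sum model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueweights)
library(dplyr)
```

## The scientific problem

When a 3D planar surface is specified simultaneously by binocular disparity
and by a texture gradient, the visual system combines the two depth cues
into a single perceived orientation. Cue-conflict ("metastimulus")
paradigms pit the cues against each other: the texture plane and the
disparity plane are given *different* slants and tilts, and the observer's
matched orientation reveals how strongly each cue contributes.

Surface orientation is parameterised by slant $\sigma$ (rotation away from
frontoparallel) and tilt $\tau$ (direction of the surface normal's
projection onto the frontoparallel plane). Because slant and tilt jointly
define a direction on the sphere, this package treats cue combination as
*vector summation of unit surface normals* rather than as independent
weighting of the two angles:

$$\mathbf{n}_p = w_t \mathbf{n}_t + w_d \mathbf{n}_d,$$

where $\mathbf{n}_t, \mathbf{n}_d$ are the unit normals specified by
texture and disparity, $\mathbf{n}_p$ is the perceived normal, and
$w_t, w_d$ are the cue weights. Requiring the combined vector to be a unit
normal itself turns the overdetermined linear system into the constraint
pair

$$\|w_t \mathbf{n}_t + w_d \mathbf{n}_d\|^2 = 1, \qquad
  \mathbf{n}_p \cdot (w_t \mathbf{n}_t + w_d \mathbf{n}_d) = 1 .$$

In the $(w_d, w_t)$ plane the first constraint is an origin-centred
ellipse whose shape depends only on the cue separation
($w_t^2 + w_d^2 + 2 w_t w_d\, \mathbf{n}_d\!\cdot\!\mathbf{n}_t = 1$,
principal axes along the $\pm\pi/4$ diagonals with semi-axes
$1/\sqrt{1 \mp \mathbf{n}_d\!\cdot\!\mathbf{n}_t}$), and the second is a
line. When the percept lies in the plane spanned by the cue normals,
Cauchy–Schwarz forces the combined vector to *equal* $\mathbf{n}_p$, so the
line is tangent to the ellipse and the solution is unique — this is the
closed form implemented in `weights_closed_form()`. When the percept lies
off the cue plane no exact solution exists and `weights_constrained()`
minimises the two constraint residuals jointly with a damped Gauss–Newton
(Levenberg–Marquardt) iteration. `weights_pseudoinverse()` provides the
unconstrained least-squares solution for comparison; it does not keep the
combined vector at unit length. A consequence of the ellipse constraint
worth emphasising is that the weights do **not** sum to one: for
non-negative weight pairs under conflict, $w_t + w_d \ge 1$ with equality
only when the cues agree.

A note on numerics: the constrained solver is initialised at the
pseudo-inverse solution radially projected onto the ellipse (cheap and
inside the attraction basin of the tangency point), weighs both constraint
residuals equally, and reports the best iterate with a warning flag in the
rare event the damped iteration stalls. Because the tangency point is a
double root, the damped normal-equations iteration alone bottoms out
around $10^{-5}$ in the weights (the valley direction is lost to
cancellation in $J^\top J$); near-solvable cases therefore get a final
Newton polish on the $2\times 2$ system itself, which is conditioned by
$\det J$ and reaches the floor of the double root. For in-plane percepts the three
solvers agree to machine-level accuracy and the unit-norm invariant holds
to $10^{-8}$; for off-plane percepts the unit-norm residual is $O(\epsilon^2)$
in the off-plane angle $\epsilon$ — the price of the joint minimisation —
which is why the conservation property is only asserted for in-plane data.
Near-parallel cues (separation under $0.5^\circ$) leave the weights
unidentifiable (any pair summing to one fits); solvers then return the
symmetric pair $(0.5, 0.5)$ flagged `degenerate` so batch pipelines keep
running, and aggregation drops and counts those trials. Negative weights
(percepts outside the cue wedge) are reported as-is, never clipped:
clipping would bias pre/post comparisons toward zero change.

## Stimulus geometry

`viewing_geometry()`, `generate_voronoi_sites()`, `backproject()`,
`stereo_project()` and `disparity_field()` implement the three-step
metastimulus construction: (1) a plane at the texture pose is textured
with a jittered-grid Voronoi pattern (which avoids regular perspective
cues), (2) its cyclopic image is projected — along cyclopic rays — onto a
second plane at the disparity pose, and (3) the result is rendered through
two horizontally offset eyes with screen-converged (off-axis) frusta. The
defining property, which the tests verify, is that the cyclopic image is
invariant to the disparity pose while the disparity field depends on the
disparity pose alone; the two cues can therefore be manipulated
independently inside one fused surface.

Conventions: the screen plane is $z = 0$ with the aperture centre at the
origin and the cyclopic eye at $(0, 0, \mathrm{VD})$; crossed (near)
disparity is positive; all file and interface angles are degrees and all
coordinates centimetres. The default viewing distance is 50 cm with
ipd 6.4 cm and a 35.5° aperture; 55 cm is an equally valid configuration
of the same apparatus and is exposed through `viewing_geometry()` rather
than hard-coded. The experimental grid sizes and jitter of the Voronoi
texture are not fixed by the task, so `generate_voronoi_sites()` exposes
both (`jitter = 0.8` by default, a typical strongly jittered grid).

## Cue-conflict configurations and designs

A configuration is a conflict centre $(\sigma_c, \tau_c)$ plus
discrepancies $(\Delta\sigma, \Delta\tau)$ split half-and-half between the
cues, with the disparity cue taking the half *toward* frontoparallel:
$\sigma_d = \sigma_c - \Delta\sigma/2$, $\sigma_t = \sigma_c +
\Delta\sigma/2$ (and likewise for tilt). With $\sigma_c = 15^\circ$ and
$\Delta\sigma = 30^\circ$ the disparity cue signals an exactly
frontoparallel plane, which is why perceived tilts are flagged undefined
below a slant of $0.1^\circ$.

`judgment_design()` crosses $\sigma_c \in \{15, 25, 35\}$,
$\tau_c \in \{0, 45, 90\}$ and the two discrepancy conditions
$[\Delta\sigma, \Delta\tau] = [30, 0]$ and $[30, 45]$: 18 configurations,
90 trials at 5 repetitions. `training_design()` produces the
direction-alignment trial tables: 24 trials for the joint-control (ATD)
group ($\Delta\tau \in \{\pm45, \pm90\}$ × 2 target axes × 3 repetitions)
and 48 for each single-control group (3 slants × 8 tilts × 2 target axes
for the fixed cue plane). The slant discrepancy maintained during ATD
training is not dictated by the task geometry; the package carries the
judgment-task value $\Delta\sigma = 30^\circ$ as its default. Trial order
is a uniform permutation under the study seed (whether the original runs
were blocked is unknowable from the design arithmetic; an unblocked
permutation is the neutral choice and the counts are order-invariant).

## The synthetic observer

No response data ship with the package, so every analysis stage is
exercised against a generative observer with known ground truth:

* a `weight_field()` maps the conflict centre to a disparity weight,
  $w_d = \beta_0 + \beta_\sigma \log\sigma_c + \beta_\tau \tau_c +
  \beta_{\sigma\tau}\tau_c\log\sigma_c$, with defaults
  $\beta_0 = 1.9$, $\beta_\sigma = -0.35$ per log-degree,
  $\beta_\tau = 0.003$ per degree, $\beta_{\sigma\tau} = 0$. The signs
  encode the two robust qualitative effects the analysis must recover —
  disparity down-weighted as the central slant grows, up-weighted as the
  central tilt rotates toward vertical — and the magnitudes keep
  $w_d \in (0, 1.5)$ over the tested grid. They are simulation choices,
  not measurements. The interaction defaults to zero so that the
  generative model and the trend-fit model coincide; a nonzero value is
  available for sensitivity studies.
* `predicted_normal()` pairs that $w_d$ with the $w_t$ lying on the
  conflict ellipse, so the noiseless percept is exactly consistent with
  the vector-sum model;
* `sample_perceived()` adds von Mises–Fisher directional noise
  (rotationally symmetric on the sphere, concentration $\kappa$; the
  sampler uses the exact inverse-CDF of the deviation cosine). The
  adjustment task has no published noise model, so a single-parameter
  symmetric family is the minimal assumption; $\kappa = 200$
  (≈ 4° angular SD) is the package default for a practised observer and
  $\kappa = 50$ (≈ 8°) is used as the stress level in the recovery
  studies;
* `simulate_study()` adds Gaussian per-subject intercepts on $w_d$
  (SD 0.1 by default), mirroring random-intercept heterogeneity without a
  mixed-model machinery, and applies the field's `post_shift` (default
  $-0.15$ in the ATD preset, i.e. reweighting toward texture) only in the
  post phase of the ATD group;
* `simulate_adjustment()` replays the touchpad dynamics of the matching
  task: touches beyond a 0.7 trigger radius set the tilt to the
  quadrant-aware touch angle and step the slant by 0.1° per frame
  (a single-argument arctangent could not distinguish opposite tilt
  directions, so the two-argument form is used), with the slant clamped
  to $[0, 89.9]^\circ$.

What the generator deliberately does *not* emulate: adaptive trial-order
effects, lapses, anisotropic response noise, motor dynamics of the
training phase, or any dependence of noise on the stimulus. Passing the
recovery tests therefore shows that the estimation and inference machinery
is correct under the stated model, not that human data obey it.

## Analysis pipeline

`estimate_trial_weights()` applies the constrained solver per trial;
`aggregate_weights()` forms cell means per subject (or pooled — both
aggregations are exposed because averaging before or after model fitting
is a genuine analytical fork), excluding and counting degenerate trials;
`fit_trend()` fits $\bar w_d \sim \log\sigma_c + \tau_c$ (tilt as additive
per-level offsets) by ordinary least squares with a subject-level
nonparametric bootstrap (percentile CIs; default 1000 replicates);
`pre_post_test()` runs a paired sign-flip permutation test of the
post-minus-pre change per cell with max-T familywise correction over each
discrepancy condition's 3 × 3 (slant × tilt) grid. The permutation
statistic is the one-sample $t$ of the subject-level differences and the
sign-flip null is exact under the symmetric response noise of the
generator. With 14 or fewer subjects the full $2^n$ flip group is
enumerated, making the $p$-values deterministic, strictly positive and
exactly invariant to subject relabeling; with more subjects `n_perm`
random flips are drawn with the add-one convention. Inversions of the weight scale (such as modelling $2 - w_d$ to fix
a distributional skew) change neither cell means nor permutation
decisions, so the pipeline works on $w_d$ directly. A deliberate design
choice: trend and pre/post inference are *implemented* (OLS + bootstrap;
permutation + max-T) rather than delegated to a mixed-model stack, so the
package's statistical claims are fully auditable and testable against
their own calibration simulations.

Problem sizes used by the shipped verification suites — chosen to give
stable Monte-Carlo estimates at interactive run times — are 100 replicate
studies (κ = 50, 10 subjects, 400 bootstrap replicates) for CI coverage
and 1000 null studies (999 sign flips each) for type-I calibration.

## A worked example

```{r example, eval = FALSE}
design <- judgment_design(repetitions = 5, seed = 1)
preset <- observer_preset("ATD")
records <- simulate_study(design, preset$field, preset$noise,
                          n_subjects = 10, group = "ATD", seed = 1)
weights <- estimate_trial_weights(records)
map <- aggregate_weights(weights)

fit <- fit_trend(filter(map, phase == "pre"), n_boot = 1000, seed = 2)
tidy(fit)

pp <- pre_post_test(map, n_perm = 9999, seed = 3)
glance(pp)
autoplot(pp)
```

`run_pipeline(run_config(seed = 1), "out/")` executes the same chain end
to end and writes every table plus a JSON manifest with the derived child
seeds and MD5 checksums of all outputs, so a run is reproducible
bit-for-bit from its configuration. The package deliberately ships no
shell entry point: the exported functions *are* the interface, and
`scripts/acceptance.R` shows the whole pipeline driven non-interactively.

## Known limitations

* The vector-sum model is purely geometric: it does not weight cues by
  reliability, and the package intentionally implements no
  maximum-likelihood or Bayesian cue-combination machinery.
* Whether off-plane percepts should be projected onto the cue plane
  before solving is an open modelling question; the constrained solver
  reports the joint-residual minimiser, and the pseudo-inverse route is
  available for comparison.
* The max-T familywise correction treats each discrepancy condition's
  nine cells as the family; other groupings are defensible.
* Synthetic magnitudes (field coefficients, κ, subject SD, post shift)
  are package conventions for exercising the machinery, not estimates of
  any observer population.
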