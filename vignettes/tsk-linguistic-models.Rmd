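---
title: "Granular TSK linguistic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granular TSK linguistic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsklm)
```

## The model

`tsklm` predicts a continuous output (energy expenditure, kcal/min) from a
small number of physiological inputs (heart rate, movement index) with a
fuzzy rule base whose rules are *extracted from data* rather than written
by hand, and whose output is a triangular fuzzy number — an interval
prediction with a modal value.

Training proceeds in five stages, all in min–max normalized `[0, 1]` space
(statistics taken from the training data only, so evaluation on held-out
data cannot leak):

1. **Contexts.** The normalized output range is covered by `p` triangular
   fuzzy sets with break points $(r_t^-, r_t, r_t^+)$ forming a partition
   of unity. The two boundary contexts are open-shouldered (membership 1
   beyond the outer apex), which is what makes the partition exact at the
   range limits; their stored outer break point is clamped to the range
   limit.
2. **Granulation.** Within each context $t$, context-based fuzzy c-means
   (CFCM) finds `c` cluster centers $v_{ti}$ in input space. The
   membership column of data point $k$ is constrained to sum to its
   context membership $w_{tk}$, so the clusters describe *where in input
   space the data of this output granule live*.
3. **Activation.** For any input $x$, fuzzy-c-means memberships are
   computed over the pooled $p \times c$ centers and summed per context,
   giving activations $z_t(x) \ge 0$ with $\sum_t z_t = 1$.
4. **Consequents.** Rule $t$ contributes $[r_t^-, r_t, r_t^+] + b_t^\top x$.
   The coefficients $b_t$ of all rules are estimated by one global least
   squares solve, because the modal output
   $f^* = \sum_t z_t (r_t + b_t^\top x) + b_0$ is linear in all of them
   jointly; a per-rule fit would not minimize the actual training error.
5. **Bias.** $b_0$ is the mean training residual of the modal output, so
   the modal prediction is exactly unbiased on the training set.

The lower and upper outputs replace $r_t$ by $r_t^-$ and $r_t^+$ with the
same activations and linear terms. Because each row of break points is
ordered and $z$ is a convex weighting, `lower <= modal <= upper` holds for
every input — this is a theorem of the construction, and the test suite
checks it on thousands of random points.

The **conventional linguistic model** baseline keeps stages 1–3 and uses
the context fuzzy number alone as consequent (no linear terms, no bias).
It is fitted through the same code path, so with a shared seed both
variants use *identical* contexts and centers; the TSK variant then
strictly generalizes it, which is why its training RMSE can never be worse
in a paired comparison. The baseline's modal output
$\sum_t z_t r_t$ with these pooled activations is a reconstruction of the
classic granular linguistic model; the original formulation leaves the
out-of-sample activation rule unstated (see "Design choices").

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `contexts` (p) | output granules | 3 (grid 2–6 in the protocol) | more granules = finer output resolution, fewer points each |
| `clusters` (c) | rules per context | 3 (grid 2–6) | input-space resolution inside a granule |
| `m` | fuzzifier | 2.0 | the standard choice; memberships soften as m grows |
| `scheme` | context placement | `"uniform"` | `"flexible"` places apexes at equal-probability quantiles |
| `tol` | max \|ΔU\| stopping rule | 1e-5 | membership changes below this do not move centers meaningfully |
| `max_iter` | CFCM sweep cap | 200 | alternation converges in well under 100 sweeps on these sizes |
| `train_fraction` | split | 0.6 | 60/40 train/check protocol |
| `iterations` | repeated splits | 10 | averages out split luck |

## Numerical choices and degenerate inputs

* **Initialization.** CFCM memberships start as uniform random draws
  rescaled per column to sum to $w_{tk}$, from a user seed; the global RNG
  state is restored afterwards. Identical seeds give bit-identical fits.
* **Tie-breaks.** A point at zero distance from one or more centers gets
  its full weight split equally among the coincident centers (both inside
  CFCM and at activation time). Distances are compared to a $10^{-30}$
  squared-distance floor.
* **Objective.** The clustering objective
  $\sum_{i,k} u_{ik}^m \lVert x_k - v_i \rVert^2$ is recorded each sweep;
  each half-update is the exact constrained minimizer given the other
  block, so the trace is non-increasing (asserted to $10^{-10}$ per step).
* **Rank deficiency.** The consequent solve uses a rank-revealing QR; if
  the design is rank-deficient (or has fewer rows than coefficients) a
  ridge with $\lambda = 10^{-8}$ on the normal equations takes over.
* **Degenerate inputs.** A constant output or input column is an error
  (min–max normalization would divide by zero); a context with no
  supported points, or more clusters than supported points, raises an
  error naming the context. During `run_experiment()` such cell failures
  are recorded and the run continues.
* **Empty-region contexts.** With a saturating output map, uniform
  contexts in the sparse low-output region often support fewer points
  than `c`; cells then fail for some splits. This is the data-scarcity
  problem that motivates the flexible (quantile) scheme, under which all
  grid cells train on all splits in our experiments. `glance()` on an
  experiment therefore compares only cells with the maximal number of
  successful iterations — means over different split subsets are not
  comparable.

## Design choices where the formulation is open

* **Out-of-sample activation.** Context memberships $w_{tk}$ are defined
  through the *observed output*, which does not exist at prediction time.
  We compute context-free fuzzy-c-means memberships over the pooled
  centers and partial-sum them per context. This matches the "sum the
  membership grades per context" architecture, guarantees
  $\sum_t z_t = 1$, and makes the output a convex combination — which is
  what makes the interval ordering provable. The same rule is used at
  training time, so training and prediction evaluate the same function.
* **Flexible contexts.** The distribution-based placement is
  operationalized as apexes at quantile levels $t/(p-1)$, $t = 0..p-1$:
  each context then carries roughly equal probability mass. Ties among
  quantiles (heavily discrete outputs) are an error rather than silently
  merged granules.
* **Activation normalization.** Whether $z_t$ should be normalized is
  ambiguous in the original formulation; pooled memberships sum to 1 by
  construction, so no explicit normalization step is needed — this is a
  documented consequence of the activation choice above.
* **Improvement metric.** Relative improvement is reported as
  $(\text{baseline} - \text{model})/\text{baseline} \cdot 100$ on mean
  RMSE at each variant's best grid cell.

## What the synthetic generator emulates — and what it does not

The study data behind this model family (chest-patch sensor, treadmill
and outdoor exercise, indirect calorimetry ground truth) are not publicly
deposited, so the package generates data with the *reported statistical
structure*: five activity regimes of `n = 76` rows; HR and MI drawn as a
bivariate Gaussian with Pearson correlation 0.892 (the value reported for
treadmill running), centred mid-range with SD one sixth of the range and
censored at the range limits; EE a saturating monotone function of a
0.6/0.4 weighted combination of normalized HR and MI plus Gaussian noise
(0.5 kcal/min for treadmill). The saturating map makes the HR–EE
relationship genuinely nonlinear, which is what gives the TSK linear
terms something to do; the moments and correlation tests compare against
the censored-normal closed forms.

Not emulated: temporal autocorrelation within a session, between-subject
heterogeneity, heteroscedastic calorimetry noise, treadmill-protocol
drift, or sensor artifacts. Passing tests on these data therefore
demonstrate the *mechanics* of the method (granulation, fitting,
interval calibration of the fuzzy number, protocol) — they do not certify
field accuracy on real physiological recordings.

The movement-index utility reduces an acceleration magnitude series to
per-second triangle areas between zero crossings (apex = the extremum
between consecutive crossings). The feature-point rule of the original
sensor firmware is proprietary to its reference implementation; ours is a
stated reconstruction with the right invariances (non-negativity,
amplitude homogeneity, sign invariance), validated in closed form on an
exact triangle wave.

## Problem sizes in the test suite

Unit tests run on 10–76-point instances; property checks use 1,000 random
probes per trained model. The protocol checks run the full grid
(p, c ∈ 2..6, both variants, 10 iterations) on one 76-row table, and the
headline comparison repeats that whole experiment on 10 independently
seeded tables — a few thousand model fits, a couple of minutes on one
CPU.

## Known limitations

* The context term $\sum_t z_t r_t$ enters the modal output with fixed
  unit coefficient and is a smooth rational (not affine) function of the
  inputs. Consequently an affine target is generally *not* in the model
  span for $p \ge 2$, and training error on noiseless affine data is
  small but not zero; with a single context ($z \equiv 1$) the least
  squares stage does recover affine structure exactly. The model is built
  for saturating, granule-structured responses, not for globally linear
  ones — for those, use a linear model.
* Interval width is inherited from the context spacing, not calibrated to
  a coverage level; the bounds are the support of the output fuzzy
  number, not a confidence interval.
* Only triangular contexts and Euclidean distances are implemented;
  possibilistic/kernelized clustering variants and automatic selection of
  `p`, `c` (beyond the evaluation grid) are out of scope.
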