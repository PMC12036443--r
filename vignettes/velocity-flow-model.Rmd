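---
title: "The velocity flow transformation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The velocity flow transformation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velflow)
```

## The problem

A developmental atlas series samples a continuously deforming anatomy at a
handful of discrete ages — for the mouse brain, typically seven stages from
E11.5 to P56.  Pairwise registrations connect neighbouring stages, but they
do not answer the questions that arise in practice: what is the mapping
between two *non-adjacent* stages, or between a stage and an age that was
never imaged?  `velflow` answers both by fitting a single time-parameterized
velocity field to the whole series at once.  Integrating that field between
any two normalized times $t_0, t_1 \in [0, 1]$ yields a diffeomorphic
mapping $\Phi_{t_0 \to t_1}$; composing it with images gives cross-stage
warps and virtual templates at intermediate ages.

## The model

The data are $K \ge 2$ point sets $P_1, \dots, P_K$ in strict row
correspondence (point $j$ of every set is the same anatomical sample),
attached to strictly increasing normalized times $t_1 = 0 < \dots < t_K = 1$.
The unknown is a velocity field $v(x, \tau)$ stored as $N$ spatial vector
images ("integration points") at $\tau_i = (i-1)/(N-1)$, each voxel holding
a $D$-vector in physical units per unit normalized time.  Trajectories obey

$$\frac{dx}{d\tau} = v(x, \tau),$$

with $v$ interpolated multilinearly in space and linearly in time between
slices.  Positions leaving the domain see the clamped boundary value, a
continuous constant extension that avoids the artificial shear a zero
padding would create at the domain edge.

### Optimization

The field starts at zero.  Each iteration sweeps the $N$ integration points;
at $\tau_i$:

1. the two series times bracketing $\tau_i$ are located (consecutive times
   $t_a \le \tau_i \le t_b$);
2. $P_a$ is warped forward from $t_a$ to $\tau_i$ and $P_b$ backward from
   $t_b$ to $\tau_i$ under the *current* field;
3. residuals $r_j = x_j^{b \to \tau_i} - x_j^{a \to \tau_i}$ are anchored at
   the pair midpoints and scaled by $1/(t_b - t_a)$ into velocity units;
4. the weighted scattered samples are smoothed into a field $U_i$ with the
   multilevel B-spline approximation below;
5. slice $i$ is updated: $v_i \leftarrow v_i + \delta\, U_i$.

Midpoint anchoring symmetrizes the update between the forward- and
backward-warped sets, and the $1/(t_b - t_a)$ scaling makes the update a
velocity, so that integrating it across the bracket reproduces the full
residual.  Only slice $i$ is touched per integration point; temporal
coupling arises implicitly because the warps in step 2 traverse the other
slices.  Updates are applied in slice order within an iteration
(Gauss–Seidel style), so later integration points already see the earlier
updates of the same sweep.

Two tie rules make the bracketing deterministic: an integration point equal
to an interior series time $t_k$ uses the left interval $[t_{k-1}, t_k]$,
and $\tau = 0$ or $1$ use the first or last interval, so the endpoint slices
still receive updates.

The per-iteration *average displacement error* is the mean over integration
points of the weighted mean residual norm (the unweighted mean is recorded
alongside it, and the per-integration-point median residual norm gives the
per-slice view).  By default the optimizer runs its full iteration budget,
matching fixed-budget practice; setting `convergence_tolerance > 0` stops
when the 10-iteration windowed mean of the error stops changing by more
than the tolerance.

### Regularization: generalized multilevel B-spline approximation

`fit_scattered_field()` converts $M$ weighted vector samples into a smooth
field.  At each level, every control point takes the confidence-weighted
local least-squares value of the residual samples,

$$P_c \;=\; \frac{\sum_s w_s\, \phi_{s,c}^2\, \delta_{s,c}}
                 {\sum_s w_s\, \phi_{s,c}^2},
\qquad
\delta_{s,c} = \frac{\phi_{s,c}\, v_s}{\sum_k \phi_{s,k}^2},$$

where $\phi_{s,c}$ is the tensor-product B-spline basis value of sample $s$
at control point $c$.  Residuals at the anchors are then recomputed, the
control mesh is doubled, and the next level fits what remains; the output is
the sum of the level fields evaluated at every voxel center.  Each vector
component is fitted independently.  Control points supported by no sample
keep a zero correction, i.e. they inherit the coarser level's value — this
is what lets a very coarse base mesh act as a strong global regularizer
while later levels add local detail only where data exist.  The scheme is
deterministic, linear in the sample values, and invariant to a uniform
rescaling of the weights.

Anchors outside the domain (which happens when warped midpoints drift past
the grid edge) are clamped to the boundary rather than dropped, so no
correspondence silently vanishes.

### Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `n_integration_points` | 11 | temporal resolution of the field; memory and per-iteration cost scale linearly in it |
| `step_size` | 0.2 | fraction of each smoothed residual field applied per update; larger is faster but can overshoot |
| `max_iterations` | 200 | fixed optimization budget |
| `convergence_tolerance` | 0 | windowed-stabilization stop; 0 disables it |
| `integration_substeps_per_slice_interval` | 4 | RK2 steps per slice interval; error falls quadratically in it |
| B-spline `order` | 3 | cubic splines, $C^2$ fields |
| B-spline `base_mesh` | 1 | one span per axis at the coarsest level: near-affine global regularization |
| B-spline `levels` | 4 | finest mesh of 8 spans per axis |

The mesh, level count, and spline order of the regularizer used for the
original atlas model were never published; they are therefore exposed as
configuration, and the defaults above were chosen once as a
strong-to-moderate regularization ladder appropriate for smooth
developmental deformations.

### Numerical integration

`integrate_velocity_field()` and `transform_points_in_time()` share one
stepping scheme: fixed-step midpoint (RK2), with
`substeps` $\times (N-1) \times |t_1 - t_0|$ steps (at least one).  The
scheme is not named by the source description of the method; RK2 was chosen
because its $O(h^2)$ global error is cheap, testable (the test suite
measures a log–log slope of $-2$ against a closed-form exponential
trajectory), and exact for space-constant fields that are at most linear in
time.  Backwards integration is the same loop with a negative step.

`invert_displacement_field()` uses the standard fixed-point iteration
$u \leftarrow -d \circ (\mathrm{id} + u)$, stopping when the mean update
norm falls below `1e-3 * min(spacing)` (configurable).  The iteration
contracts when the deformation's Jacobian stays in the invertible regime;
five consecutive growths of the update norm abort with an error advising a
smaller deformation, since proceeding would silently return garbage.

## Temporal normalization

Developmental ages are unevenly spaced, with postnatal gaps dominating.
`normalize_time_points()` optionally log-transforms the ages before min–max
normalization, which converts age *ratios* into normalized *differences*
and evens out the sampling.  Two conventions are involved for the default
seven-stage series:

* P56 enters as 28 days — brain shape changes little after the fourth
  postnatal week, so letting the true 56-day age dominate the normalized
  axis would waste most of the temporal domain on a nearly rigid interval;
* postnatal day $d$ is placed at $18.5 + d$ continuous days (birth at
  E18.5).  The embryonic/postnatal concatenation offset is not published;
  `devccf_postnatal_offset_days()` documents the package's choice and
  `devccf_default_days(postnatal_offset = ...)` lets users override it.

With both conventions the default ages are
(11.5, 13.5, 15.5, 18.5, 22.5, 32.5, 46.5).

## Point extraction from label volumes

`sample_label_points()` reproduces the label-guided sampling recipe:
per label, boundary voxels (face adjacency — 6-connectivity in 3-D, with
out-of-volume neighbours counting as background) are sampled without
replacement at 10% and interior voxels at 1%, with boundary points weighted
twice.  Counts are `round(rate * n)` with a floor of one per non-empty
stratum, per label — the stratification is per label rather than global,
which guarantees every region contributes points regardless of its size
(the source description does not say which variant was used; per-label is
the choice here, and it is the stricter one for small structures).  The
draw is seeded and fully reproducible; ids encode label, stratum, and
index, so downstream propagation keeps the correspondence auditable.

The rigid pre-normalization of stages is reduced to
`label_centroid_translation()`: a translation by the difference of
shared-label centroids.  Rotation estimation is deliberately absent — the
synthetic verification does not exercise it and the atlas workflow supplies
externally computed pairwise registrations anyway (via
`propagate_points()`).

## What the synthetic generators emulate — and what they do not

`generate_flow_series()` produces point sets moving under analytic
translation, rotation, radial expansion, or sinusoidal flows, with optional
independent per-time-point jitter that mimics annotation/section noise
(jitter along trajectories would be the wrong model: annotation error does
not follow the anatomy).  The returned ground-truth evaluator gives exact
trajectories, so recovery error, inverse consistency, and Jacobian
positivity can be measured against truth rather than against the model
itself.

What these generators do *not* emulate: anisotropic and regionally
heterogeneous growth, topology-adjacent deformations near ventricles,
intensity artifacts, or correspondence errors from imperfect registrations.
Passing the recovery suite therefore demonstrates that the optimizer and
integrator implement the model correctly at realistic magnitudes — not that
the model resolves every difficulty of real developmental data.

## Study sizes used by the verification suite

The packaged checks run at desk scale, chosen to exercise every code path
in minutes on one core: $64^3$ grids with 200–500 points for recovery
(translation at $N = 5$, 100 iterations; radial expansion at $N = 7$, 120
iterations — the radial flow is affine, so a moderate temporal resolution
resolves it and the error plateaus well before the budget), $48^3$ for the
virtual-template check, and small 2-D grids for unit-level properties.
The original atlas model was fitted at $[256, 182, 360]$ voxels (50 µm
isotropic) with $N = 11$ over 200 iterations on ~173k points — the same
code paths at roughly three orders of magnitude more voxel work.  One
source passage reports ten integration points where another reports eleven;
the package defaults to 11 and leaves it configurable.

## Known limitations

* The fit is landmark-driven only; there is no image-intensity term.
* Direction matrices other than the axis-aligned identity are rejected:
  the model lives in a template space, and supporting oblique orientations
  would add surface area without exercising the method.
* The multilevel B-spline update is an approximation, not an exact
  interpolation; exactness at the anchors is approached only in the
  many-level limit.
* Virtual templates are voxelwise weighted averages of pre-warped images;
  no registration-based shape refinement is applied on top.
* Velocity fields are stored as 32-bit float on disk (matching common
  practice and the published model's ~2 GB footprint at atlas scale), so
  round trips are exact only to single precision.
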