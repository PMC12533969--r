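---
title: "Models and methods behind bcivmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcivmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the simulator, the analysis definitions, the numerical choices,
and what the synthetic data can and cannot tell you about recordings from a
real brain–computer interface (BCI) experiment.

## The task and coordinate conventions

The simulated task is a memory-guided 3D center-out reach under BCI
control. Eight targets sit at the vertices of a 70 mm cube centered on the
fixation point; each trial runs through a cue (300 ms), a fixed planning
period (400 ms), a variable delay (0–600 ms), and a movement period, all
binned at the 50 ms loop period of the decoder. The visuomotor rotation
(VMR) rotates the cursor by a fixed angle (default 30°) about the depth
axis, i.e. only in the fronto-parallel X–Y plane.

Coordinates are right-handed: X rightward, Y upward, Z toward the subject.
Counterclockwise (CCW) is a positive rotation about +Z. A session applies
one rotation direction throughout; all cross-session statistics operate in
the shared target-frame (below), where the perturbation axis is oriented by
the session's rotation sign so CW and CCW sessions average coherently.

## The generative model

**Tuning.** Each unit fires with expected count per 50 ms bin

$$\lambda_i(t) = b_{0,i} + \mathbf{b}_i \cdot \mathbf{v}(t),$$

the classic linear velocity-tuning model that also underlies the decoder's
observation equation. Preferred directions are drawn approximately
uniformly on the sphere; tuning norms are uniform on
0.004–0.012 counts/bin per mm/s, giving modulation depths comparable to the
baseline rate at the task's peak speed. Baselines are drawn on
0.5–2 counts/bin (10–40 spikes/s) and floored at 1.05 × ‖**b**‖ × 165 mm/s
so expected rates never rectify at zero inside the task's speed range —
tuned cells modulate around an elevated baseline, and the floor keeps the
rate model linear where the Kalman filter assumes it. During planning, the
directional term is scaled by a planning gain (default 0.7) and driven at a
nominal 200 mm/s toward the (re-aimed) target; hold-period cursor position
stays at the fixation point.

**Latent structure.** Counts add a shared low-dimensional term
L·z(t) with z ~ N(0, I) and rank-4 loadings (sd 0.15 counts/bin), so the
manifold analyses have genuine low-dimensional covariance to detect — the
rank matches the four principal components the alignment analyses use.
Private Gaussian noise (sd 0.3 counts/bin) is added, and counts are rounded
and clipped at zero. A Poisson option exists; Gaussian is the default
because calibration is least squares (which does not require Poisson
statistics) and because it keeps the oracle math exact. The fully
deterministic limit (`noiseModel = "none"`) returns un-rounded expected
rates so that the calibrate–decode identity is exact; it exists for
geometric checks, not as a model of data.

**The command and the closed loop.** The intended command follows a
minimum-jerk speed profile (700 ms nominal duration) toward the target
direction rotated in-plane by the current aim offset. Minimum jerk is not a
claim about the animals — any smooth bell-shaped profile would do — it is
simply the standard choice. Controlling units' counts are decoded by the
velocity Kalman filter; the cursor velocity is the decoder output rotated
by the applied VMR during rotation-phase trials; positions integrate
velocity per bin. Within a trial the command is open-loop (no online
corrections); the loop closes *across* trials through learning.

**Learning as re-association.** A single scalar aim angle, shared by the
population, updates after every trial:

$$\text{aim} \leftarrow \rho \cdot \text{aim} - \eta \cdot \alpha,$$

with retention ρ (default 0.995), learning rate η (default 0.02), and α the
trial's signed midpoint angular error (CCW-positive). The fixed point under
a rotation R is −ηR/(1 − ρ + η), so the asymptotic compensation never
exceeds the rotation. Defaults give a plateau around 80–90% compensation
over a 300-trial rotation phase, the scale of adaptation the protocol is
built around; the test fixtures use η = 0.05, ρ = 0.99 so short sessions
reach their plateau quickly. Noncontrolling populations express the shared
aim scaled by a per-population *adaptation gain* in [0, 1] — the
re-association account reduces exactly to per-population scalings of one
compensatory rotation, which is also what makes relative gains a meaningful
readout. A `frame` switch per population generates the three competing
hypotheses for what noncontrolling units encode: `motor` with gain 0
(stationary), `visual` (the rotated feedback), `motor` with gain > 0
(re-association).

The generator is agnostic about whether compensation is explicit re-aiming
or implicit recalibration; it produces the aim offset regardless of
mechanism, which is all the downstream analyses consume.

## The decoder

Calibration regresses each unit's counts on (vx, vy, vz, 1) — the constant
column absorbs b0 — with the residual covariance as observation noise Q;
the state transition is the least-squares fit of v_t on v_{t−1} (pairs
never straddle trial boundaries) with its residual covariance as process
noise W. The state is 3D velocity plus a constant-1 channel that the filter
never updates (A[4,4] = 1, zero process noise and prior variance); position
is obtained purely by integration, because the observation model contains
velocity only.

Numerical choices: the initial velocity covariance is isotropic at 10× the
mean process-noise variance (isotropy makes decoding exactly equivariant
under workspace rotations); the first 2 bins are treated as filter burn-in
in error metrics; Q receives a tiny diagonal floor (max(1e−8, 1e−10·mean
diag)) so the innovation covariance stays invertible in the noiseless
limit, where H·P·Hᵀ has rank ≤ 4; near-singular calibration regressors
trigger a ridge fallback with a loud warning. Because H, Q, A, W are fixed,
the Kalman gain sequence is data-independent and is precomputed once per
decoder, which is what makes whole-session simulation cheap.

Assisted control is the weighted vectorial sum w·computer + (1−w)·decoded
with a monotone schedule ending at zero computer weight, mirroring how
control is gradually handed to the brain during retraining; retraining
itself regresses counts on unit-norm cursor-to-target vectors at a nominal
200 mm/s (the protocol does not pin this speed; it is configurable).

## Behavioral measures

Trajectories are first projected onto the perturbation plane, then
expressed in the basis (center→target in-plane direction, orthogonal
in-plane direction), the orthogonal sign oriented toward the applied
rotation. The midpoint angular error α is the signed angle of the position
at 50% of *cumulative path length* relative to the center–target line;
path length is the default because it is robust to asymmetric speed
profiles, with a normalized-time variant behind a flag since the definition
is genuinely ambiguous. Deflection is the perturbation-axis coordinate at
the sample closest to a given fraction of normalized movement *time*
(traces are conventionally plotted against percent of movement), with a
path-length variant behind a flag. Averaging resamples each trajectory to
100 points by linear interpolation over normalized time (the count is a
convention, not a result) and keeps the per-point samples for bootstrap
bands.

## Offline reconstruction

The offline decoder is always trained on baseline activity of the selected
population and applied to the test phase; baseline evaluation is
leave-one-out so every baseline trial is reconstructed by a decoder that
never saw it. Movement-period training targets are the *realized* cursor
velocities (during unperturbed baseline the motor command and the visual
feedback are spatially congruent, which is exactly why baseline training
cannot bias the readout); memory-period training targets are unit-norm
vectors toward the cued target, so memory reconstructions are in arbitrary
units.

Memory-period bins are conditionally independent given the static target,
and the within-trial training "velocities" are constant — the fitted AR
transition is the identity with zero residual, which degenerates the
filter's prior. Planning bins are therefore decoded by per-bin
maximum-likelihood inversion of the calibrated observation model, i.e. the
Kalman update in its uninformative-prior limit.

"Late rotation" means the last 50% of rotation trials. The 8-way classifier
assigns the target nearest the reconstruction endpoint, ties broken by
lowest index and flagged; because the eight targets are equidistant from
the origin, nearest-target classification is effectively directional, which
is why arbitrary-unit memory reconstructions classify cleanly. The aiming
vector sums unit-normalized decoded directions over the final 400 ms of
planning, skipping (and reporting) zero-norm bins. Relative gain divides a
population's final mean reconstructed angle by the controlling
population's; it is flagged undefined when the controlling angle is below
0.5°, as in baseline phases.

Only successful trials enter any reconstruction; the simulator currently
marks all trials successful, so this filter is load-bearing only for data
imported from elsewhere.

## Manifold analyses

The covariance substrate is trial-averaged (per target) activity over the
epoch's bins, concatenated across targets, soft-normalized per unit by its
firing-rate range plus 5 spikes/s (the conventional soft-normalization
constant; the procedure is not pinned by the protocol), and mean-centered.
Variable-delay bins are dropped so planning epochs align across trials.
The alignment index of epoch 2 against epoch 1's top-n PCs is
tr(Pᵀ C₂ P) / Σ top-n eig(C₂) ∈ [0, 1]; the baseline reference value is
cross-validated (PCs from one random half of baseline trials, variance
ratio from the other, averaged over 10 splits) so estimation noise is not
mistaken for manifold change. Two component-count conventions coexist —
top-4 (default) and enough PCs for 90% of reference variance — because both
are in common use; they are exposed side by side.

A caveat the implementation makes explicit: pooling subpopulations with
*different* adaptation gains genuinely perturbs the pooled covariance (each
subpopulation's tuning rotates by a different angle, and the union of the
rotated subspaces leaves the original manifold), so manifold-preservation
statements are evaluated per homogeneous population (controlling, M1–PMd
noncontrolling, PRR noncontrolling).

## Statistics

Adaptation curves are fit as α(t) = a·exp(b·t) by Levenberg–Marquardt
nonlinear least squares with multi-start initialization over a small decay
grid. Inference is a session-clustered bootstrap (2,000 resamples by
default; p-values from the sign distribution of the resampled estimates)
because pooled intercept/decay estimates need clustering to respect
session-level dependence; with one session, trials are resampled instead.
The same machinery verifies the *absence* of a baseline trend.

Deflections are tested per population with a two-sided one-sample t test on
per-session means. Preferred-direction (PD) shifts regress counts on the
intended straight-to-target command per phase and report the in-plane angle
change, rotation minus baseline, excluding weakly tuned units below a norm
threshold. Under re-association the PD measured this way shifts by −gain ×
aim — in the *direction of the applied rotation*, because that is precisely
the remap that implements the behavioral compensation.

The planning→movement relation pairs the memory-reconstruction deflection
at the end of planning (arbitrary units, final 400 ms) with the movement
deflection 200 ms after go (early, to limit feedback-driven corrections;
window edges snap to the 50 ms grid), rotation trials only. The
hierarchical model is `movement ~ planning + planning:trial +
(1 | animal/session)`; with a single simulated animal the nested grouping
is degenerate and the model drops to `(1 | session)`, and if the mixed fit
fails it falls back to fixed session effects, flagged in the result.
Pairwise population slopes come from per-pair interaction models,
Bonferroni-corrected over the six population pairs. Firing-rate stability
across phases uses a rank-sum test on per-session means and refuses
single-session input.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
linear velocity tuning with uniform PDs, a genuine low-rank shared
covariance, per-population re-association with configurable gain, planning
tuning, and the baseline → rotation → washout schedule with a negative
aftereffect. Passing tests therefore demonstrate that the estimators
recover what this model generates at the protocol's scale — parameter
recovery, not biological replication. Real recordings differ in ways the
generator deliberately omits: non-Poisson bursting and history dependence,
tuning nonlinearity and rectification, slow drifts and unit attrition,
online feedback corrections within movements, eye movements, and failed
trials. In-vivo effect magnitudes (deflections of several mm, relative
gains between 13% and 94%) depend on recorded populations and are treated
as scale anchors for defaults, never as targets to reproduce.

## Problem sizes

Unit tests run on a tiny fixture (8 units, 24 trials) and a mid-scale
fixture (48 units, 200 trials, fast learner). The protocol-scale analyses
use 96 units over three areas and the 160/300/160 schedule; the acceptance
script simulates 20 such sessions for the manifold-preservation quantity
and one noiseless non-learning session for the geometric-forcing quantity.
These sizes were chosen so a complete run is comfortable on a laptop while
keeping per-target trial counts (~20 per phase) large enough for stable
covariance and regression estimates.
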