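---
title: "Predictive gait dynamics: model, assumptions and numerical choices"
author: "gaitdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive gait dynamics: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdyn)
```

## What the package models

`gaitdyn` predicts sagittal-plane walking dynamics — hip and knee joint
angles, per-foot ground reaction forces (GRF), and ankle/knee/hip joint
moments — over a full, periodic, bilaterally symmetric gait cycle, from three
numbers a clinician can obtain without instrumentation:

* leg length $l$ (ASIS to medial malleolus, metres),
* body mass $M$ (kg),
* walking cadence $f$ (strides per second), giving the gait period $T = 1/f$.

The intended use is reconstructing an individual's *premorbid* normal gait
pattern as a reference for rehabilitation planning and assistive-device
tuning, where instrumenting the patient's healthy gait is impossible by
definition.

## Joint kinematics: truncated Fourier series

The left hip or knee angle is a truncated Fourier series, linear in leg
length:

$$\phi_L(t) = B_0\,l + \sum_{j=1}^{n} B_j\,l\,\sin(2\pi j f t + \varphi_j),$$

with the right side obtained by replacing $\varphi_j$ with
$\varphi_j + j\pi$ — algebraically identical to a half-period delay, which is
the bilateral-symmetry assumption in closed form. Three harmonics are used
for hip and knee ($n = 3$); a fourth would be used for the ankle, but no
ankle coefficients are shipped because the kinetic model treats each stance
leg as a rigid rod and ignores the foot, so ankle kinematics are never
needed downstream. The shipped hip/knee coefficient sets
(`default_angle_models()`) are population estimates from healthy adults; the
amplitudes are in rad/m so one table scales to any subject through $l$.

`fit_fourier_coefficients()` re-estimates coefficients from a measured
trajectory by ordinary linear least squares on the basis
$\{1, \sin(2\pi jft), \cos(2\pi jft)\}$, solved by QR decomposition, then
converts $(a_j, b_j)$ to amplitude–phase form. That form is non-unique:
$(B_j, \varphi_j) \equiv (-B_j, \varphi_j + \pi) \equiv (B_j, \varphi_j + 2\pi)$.
The canonical representative used throughout places every phase in
$(-\pi/2, \pi/2]$, with the amplitude sign absorbing half-turn shifts. This
band was chosen because it is the one containing the shipped population
phases, so refitting a synthesized trajectory reproduces the shipped tuples
sign-for-sign; a $(-\pi, \pi]$ band would not determine signs uniquely.
Exactly-zero harmonics report phase 0. Comparisons between coefficient sets
should nevertheless always be made on reconstructed signals, which are
invariant to the representation.

All internal angles are radians; degrees appear only in CSV files
(`write_gait_cycle()`, `read_angle_models()` ecosystem), matching common
motion-capture exports.

## Anthropometry

Segment masses, lengths and centroid offsets come from a configurable
fraction table (`anthropometric_table()`):

* per-limb thigh and shank mass fractions of body mass (defaults 0.100 and
  0.0465, the classic Dempster adult proportions); the trunk–head–arms
  remainder $m = M(1 - 2(c_t + c_s))$ is a point mass,
* thigh/shank length fractions of the measured leg length (defaults
  0.53/0.47),
* proximal centroid fractions per segment (defaults 0.433),
* the rigid stance-rod centroid $p_1$, by default the mass-weighted centroid
  of thigh plus shank implied by the other fractions, and the double-support
  leading-leg centroid $p_{2d}$, by default the mirror $l_1 - p_1$,
* gravitational acceleration (default 9.81 m/s²).

National body-segment-parameter standards publish comparable coefficient
sets; any of them can be supplied via the table arguments or a flat
key-value file (`read_anthropometric_table()`). Mass conservation
($m + 2(m_t + m_s) = M$) and length conservation ($l_2 + l_3 = l$) are exact
by construction. Segments are point masses at their centroids: no rotational
inertia about segment centroids is modelled anywhere, consistent with the
concentrated-mass construction of the chains.

## Kinetic chains and sign conventions

Two planar point-mass chains cover the cycle:

* **Single support** (three coordinates): rigid stance rod from the ground
  contact to the hip carrying the lumped leg mass $m_t + m_s$ at $p_1$ and
  the trunk point mass at its tip; swing thigh and swing shank hanging from
  the hip.
* **Double support** (two coordinates): trailing rod anchored at its ground
  contact (trunk at its tip), and the leading leg rigidified into one rod of
  length $l_1$ whose centroid sits $p_{2d}$ from the hip.

Coordinates are angles from the vertical, positive when the distal end of a
segment is anterior to its proximal end; the supporting foot contact is the
origin, $x$ anterior, $y$ up. One consequence deserves emphasis: for a
*ground-to-hip* rod the distal end is the hip, so its coordinate is the
**negative** of that limb's hip angle — a flexed hip at heel strike puts the
foot ahead of the hip, as it must. Swing and leading segments run hip-to-ground
and take the hip/shank angles directly. The rigid-leg orientation in
double support is taken from the thigh (hip) angle; since the knee is close
to extension around heel strike and toe-off, the chord-versus-thigh
difference is small, and this choice keeps every derivative analytic.

Every mass position has the form $x_k = \sum_i A_{ki}\sin\theta_i$,
$y_k = \sum_i C_{ki}\cos\theta_i$ for constant matrices built from the
segment set, so velocities, accelerations, configuration Jacobians and
energies share one code path, and all time derivatives are analytic —
numerical differentiation exists only inside test oracles.

Because the two predicted rod angles over-determine the closed double-support
chain, no loop closure is enforced: the predicted leading foot does not land
exactly on the ground. The residual is exposed per sample as
`cycle$diagnostics$ground_residual_y` rather than silently projected away.

## Ground reaction forces

Totals follow Newton's second law over all point masses:
$GRF_y = Mg + \sum_k m_k \ddot y_k$ and $GRF_x = \sum_k m_k \ddot x_k$, per
phase chain. In double support the total is split per foot by the linear
mass-transfer assumption: with $s(t) = (t - t^{hs})/T_{DT}$ rising 0 to 1
across the window,

$$GRF_y^{s1} = Mg(1-s) + \tfrac{m}{2}\ddot y_c + (m_t+m_s)\ddot y_{s1},
\qquad
GRF_y^{s2} = Mg\,s + \tfrac{m}{2}\ddot y_c + (m_t+m_s)\ddot y_{s2},$$

which sums to the two-link total identically (tested to $10^{-9}$ N). The
published horizontal split weights *both* legs' inertia by $s$,

$$GRF_x^{s1} = \tfrac{m(1-s)}{2}\ddot x_c + (m_t+m_s)\,s\,\ddot x_{s1},
\qquad
GRF_x^{s2} = \tfrac{m(1+s)}{2}\ddot x_c + (m_t+m_s)\,s\,\ddot x_{s2},$$

and therefore conserves the two-link horizontal total only at $s = 1$; the
shortfall is exactly $(s-1)(m_t+m_s)(\ddot x_{s1}+\ddot x_{s2})$. This is
implemented verbatim as the default — fidelity over correction — with the
residual returned as the `fx_residual` diagnostic column, and a clearly
non-default `variant = "conserving"` (trailing inertia weighted $1-s$) for
sensitivity analysis only. The swing foot carries identically zero force.
Forces are reported both in newtons and normalised to body weight $Mg$.

## Joint moments

Moments come from the Euler–Lagrange equations of the chain Lagrangian
$L = E_{kin} - E_{pos}$, with $E_{kin} = \tfrac12\sum m_k(\dot x_k^2+\dot y_k^2)$
and $E_{pos} = \sum m_k g y_k$ (origin as zero potential). For point-mass
chains the Euler–Lagrange left-hand side collapses to the Jacobian-transpose
form

$$Q_i = \sum_k m_k\left(\ddot x_k\,\partial_{\theta_i} x_k +
(\ddot y_k + g)\,\partial_{\theta_i} y_k\right),$$

assembled in closed form. An independent oracle in the test suite evaluates
$\frac{d}{dt}\partial_{\dot\theta_i}L - \partial_{\theta_i}L$ purely from the
energy functions by finite differences and agrees within $10^{-4}$ relative
on random smooth trajectories; a second test integrates the unforced chain
forward (deSolve) and checks energy conservation, validating the energy
functions independently of the inverse dynamics.

The generalized forces are differences of adjacent joint moments, giving the
triangular solves $M_k = Q_3$, $M_{h2} = M_k - Q_2$, $M_a = M_{h2} - Q_1$
(single support) and $M_a^{lead} = Q_{2d}$,
$M_h^{trail} = M_a^{lead} - Q_{1d}$ (double support). The rigidified stance
knee has no coordinate of its own; its moment is recovered from the same
limb's ankle and hip moments by the lever-arm decomposition
$M_k^{stand} = M_a\,l_3/l_1 + M_h\,l_2/l_1$, applied in both stance
sub-phases. The chains define no hip moment for the stance/leading leg and
no ankle moment for the trailing/swing leg, so the per-phase decomposition
feeds $M_k^{stand}$ the two moments the phase actually computes ($M_a$ and
$M_{h2}$ in single support, $M_a^{lead}$ and $M_h^{trail}$ in double
support), and the assembled per-limb cycle series carry `NA` at
joint–phase combinations the model leaves undefined, rather than a
fabricated zero. The swing ankle is the exception: with the foot excluded
from the model its force and moment are structurally zero, and the
per-foot GRF is written as 0 there.

## Cycle assembly and symmetry

The default schedule allocates 12% of the cycle to each double support and
38% to each single support, in half-open intervals starting at left heel
strike, on an even grid of 100 samples per cycle (configurable). Only the
first half cycle is computed dynamically (ds1: left leading, right trailing;
ss1: left stance, right swing); the second half is the first with the limbs
exchanged, so every right-side series is constructed as the left-side series
rotated by exactly half a cycle — the invariant is bitwise, not approximate,
for forces and moments, and an analytic identity for the angles.

`transition_discontinuity()` quantifies step-to-step smoothness: the jump of
every signal across the four phase boundaries. Two boundaries behave
qualitatively differently, and that asymmetry is informative. At heel strike
(ss→ds) the trunk stays anchored to the same rod (the new trailing leg) and
the total vertical GRF is nearly continuous. At toe-off (ds→ss) the trunk
point must re-anchor from the trailing rod to the new stance leg, whose hip
angle differs, so trunk height and acceleration change discontinuously and
the total GRF jumps by a substantial fraction of body weight. This is a
structural property of anchoring the trunk to one leg at a time — whichever
leg is chosen — not an implementation artifact; the per-foot mass-transfer
split exists precisely to smooth the *per-foot* load handoff, and the
diagnostic reports rather than hides the remaining model discontinuity.

## Synthetic pseudo-measurements

`generate_trials()` emulates the statistical structure of a validation data
set: $n$ repeated trials (default 8) equal to the predicted cycle plus
independent Gaussian noise per sample, on the common percent-gait grid, with
optional per-trial circular phase jitter (off by default). Default noise
levels are field-realistic measurement scales: 1° on angles, 2% of body
weight on forces, 0.02 N·m/kg on moments. Trial averaging
(`average_trials()`) is the pointwise mean. What this generator deliberately
does *not* contain: biomechanically structured inter-trial variability,
soft-tissue artefact, asymmetry, or non-periodicity — so tests passing on it
demonstrate correctness of the fitting/averaging/scoring machinery under the
model's own assumptions, not robustness to real gait variability. The
generator is seeded and bit-reproducible, and restores the caller's RNG
state.

## Evaluation metrics

`rmse`, `rrmse` (RMSE over the *measured* signal's range, percent) and
`pearson_rho` (centred cross-product form) implement the standard gait
waveform agreement metrics; `metrics_report()` applies them column-wise and
attaches per-sample absolute-error series so users can run waveform-level
statistics (e.g. SPM) externally — SPM itself is out of scope. rRMSE and the
correlation are undefined for constant measured signals and error (scalar
API) or return `NA` (report API) rather than guessing.

## Numerical choices and problem sizes

* Least squares via QR (`qr()`/`qr.coef`), with an explicit rank check that
  turns degenerate sampling designs into an informative error.
* Default grids: 100 samples/cycle for assembly (even, so half-cycle shifts
  are whole samples), 101-sample closed grids for fitting demonstrations.
* Test oracles use central differences with step $10^{-6}T$ for first
  derivatives and $10^{-4}T$ for second derivatives (the smaller step would
  amplify rounding error as $\varepsilon/h^2$ past the comparison
  tolerance); oracle suites run on the order of a hundred random smooth
  trajectories per chain, which keeps the full test suite under a minute.
* The worked default subject is mass 58.7 kg, leg length 0.89 m, cadence
  0.92 strides/s — a typical healthy-adult cohort mean mass, the standard
  ASIS–malleolus proportion of a 1.68 m stature, and a self-selected pace of
  about 110 steps/min.

## Known limitations

* Perfect periodicity and bilateral symmetry are assumptions, not findings;
  the model cannot represent pathological or asymmetric gait and is meant as
  a healthy-reference comparator.
* The foot is ignored: no centre-of-pressure progression, no ankle
  kinematics, swing-ankle dynamics structurally zero.
* Sagittal plane only; mediolateral forces are not modelled.
* The double-support chain is over-determined by the two predicted leg
  angles; the unclosed-loop residual and the toe-off re-anchoring
  discontinuity (both reported as diagnostics) are the price of using the
  empirical angle model unmodified in both phases.
* The published horizontal double-support split does not conserve the
  horizontal total mid-phase; it is reproduced as published, with the
  residual exposed.

```{r example}
cyc <- predict_cycle(default_subject())
cyc
summary(cyc$grf$left_fy_bw[cyc$phase != "ss2"])
head(transition_discontinuity(cyc)[, c("signal", "boundary", "jump_normalised")])
```
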