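---
title: "The walking balance-control model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The walking balance-control model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbalance)
```

# The model

`gaitbalance` treats the walking body as a planar inverted pendulum whose
controlled point is the whole-body center of mass (COM) and whose input is
the zero-moment point (ZMP), the point on the ground where the horizontal
moment of the ground reaction vanishes. With the COM at constant height $z$
the classic linearized dynamics are $\ddot x = \zeta^2 (x - x_{ZMP})$ with
$\zeta = \sqrt{g/z}$. Human stepping, however, is not front-back symmetric:
the trajectory that falls away from an equilibrium and the trajectory that
recovers toward one have visibly different slopes in the $(x, \dot x)$
phase plane. The package therefore uses the asymmetric form

$$\ddot x = \zeta_1 \zeta_2\, (x - x_{ZMP}) + (\zeta_1 - \zeta_2)\, \dot x,$$

whose state matrix $\begin{pmatrix}0 & 1\\ \zeta_1\zeta_2 & \zeta_1-\zeta_2
\end{pmatrix}$ has eigenvalues $+\zeta_1$ (divergent mode) and $-\zeta_2$
(convergent mode) with eigenvector directions $(1, \zeta_1)$ and
$(1, -\zeta_2)$. The symmetric model is the special case
$\zeta_1 = \zeta_2$, and every asymmetric formula in the package reduces to
its symmetric counterpart exactly in that limit (this is one of the
property suites in the tests).

Under this dynamics the *capture coordinate* $\xi = x + \dot x / \zeta_2$
— whose value is the capture point, the spot where holding the ZMP brings
the COM asymptotically to rest — obeys the scalar unstable equation
$\dot\xi = \zeta_1(\xi - x_{ZMP})$. That is the key to both the controller
and the identification.

## The stepping controller

During a step the controller must (a) keep the ZMP close to the support
foot $x_P$, because the physical ZMP cannot leave the support area, and
(b) make the capture point arrive at the intended landing position
$x_{Sd}$ at the landing time $T$. Minimizing
$\int_t^T (x_{ZMP} - x_P)^2\,dt$ subject to $\xi(T) = x_{Sd}$ is a scalar
linear-quadratic problem with the exact state-feedback solution

$$x_{ZMP}(t) = x_P + \frac{2\left(x_{CP} - e^{-\zeta_1 (T-t)}
x_{SP}\right)}{1 - e^{-2\zeta_1 (T-t)}},\qquad
x_{CP} = \xi - x_P,\quad x_{SP} = x_{Sd} - x_P.$$

Both $x_{CP}$ and $x_{SP}$ are foot-relative, so the law's output is also
foot-relative; the package re-anchors it by adding $x_P$, making the
anchoring explicit rather than implicit. Two limits are useful anchors for
intuition and tests: as $T - t \to \infty$ the command tends to
$x_P + 2\,x_{CP}$ (the pure braking law that reflects the capture point
about the foot), and a state already on the discounted capture manifold
($x_{CP} = e^{-\zeta_1(T-t)} x_{SP}$) needs no ZMP offset at all.

The denominator vanishes as $t \to T$, so the remaining horizon is floored
at $\varepsilon$ = 1 ms. The floor matters: the closed loop must satisfy
the terminal condition $|\xi(T) - x_{Sd}| < 10^{-3}$ m, and numerically it
does with $\varepsilon$ = 1 ms (error $\approx 4.5\times10^{-4}$ m for a
0.3 m step) but not with a floor on the order of the 60 Hz sample period
($\approx 4.5\times10^{-3}$ m). The closed-loop simulator integrates the
asymmetric equation of motion above — the law is exactly optimal only
under that dynamics, and the terminal property holds only there.

For continuous walking the law is instantiated per leg and switched by the
gait phase. A switching window runs from one leg's toe-off to the opposite
leg's toe-off, so it spans the double-support interval; within the window
the task anchor changes at the intervening heel contact (support foot
before it, freshly landed foot after it, with the horizon moving to the
next landing). Windows therefore tile time with exactly one active leg at
every sample.

# Sensor-side ZMP

Four six-axis plates (toe and heel plate per foot) give positions $x_i$,
forces $f_i$ and torques $n_i$; the moment-balance ZMP is

$$x_{ZMP} = \frac{\sum_i \{-n_{iy} - (z_i - z_{zmp}) f_{ix} + x_i
f_{iz}\}}{\sum_i f_{iz}}.$$

`measured_zmp()` also retains an alternate lever-arm variant
(`form = "alternate"`, with $x_i f_{ix}$ in place of $x_i f_{iz}$) for
comparison; the standard moment balance is the default and is the form
whose convexity, round-trip and frame-equivariance properties are tested.
When the total vertical force falls below a threshold (default 3% of body
weight — small enough to catch real contact, large enough to be robust to
the synthetic noise model) the sample is flagged as flight and no ZMP is
returned.

# Gait-phase detection

The seven Perry phases are detected per leg by a state machine whose
transitions each have a force criterion and a kinematic criterion. The
force criterion is primary whenever plate channels are present; the
kinematic criterion (computed from the rigid insole-outline model) is the
fallback and a cross-check, with disagreements beyond 5 samples collected
in a diagnostics table. In cycle order: initial contact at a heel-force
rise; loading response ends at the toe-force rise (foot flat); mid-stance
ends at the heel-force fall (heel rise); terminal stance ends at the
opposite foot's initial contact; pre-swing ends at the toe-force fall
(toe-off); initial swing ends when the swinging ankle passes the support
ankle along the travel direction; mid-swing ends when knee and ankle align
vertically; terminal swing ends at the next initial contact.

Transitions may chain within one sample, which is how the detector
reproduces the known degeneracies of a stepping start: with no opposite
initial contact the pre-swing collapses to zero duration, and with the
feet side by side the ankle-passing condition is met at toe-off, so
initial swing collapses too.

Thresholds (all configurable, all recorded in output metadata): floor
contact 10 mm, foot flat 25 mm, swing clearance 20 mm, force threshold 3%
body weight, knee-ankle alignment 20 mm, debounce 3 samples. The travel
direction used by the swing rules is the horizontal COM velocity smoothed
over roughly one gait cycle, so lateral sway does not tilt the axis.

`cycle_statistics()` normalizes each initial-contact-to-initial-contact
cycle to 100% and reports per-phase percentages and the stance/swing
split. Cycles overlapping the first or last heel contact of a bout are
flagged as walk-start/walk-stop transients and excluded by default, since
the phase sequence is degenerate there.

# Identification

`fit_balance_controller()` estimates $(\zeta_1, \zeta_2)$ and one support
anchor $x_P$ per sub-segment by least squares between the model ZMP,
evaluated along the *measured* COM trajectory, and the sensor ZMP. Because
the law is affine in $x_P$, each anchor has a closed-form conditional
optimum, leaving a 1- or 2-dimensional outer problem over the eigenvalues.
That outer problem is solved by bounded quasi-Newton iterations from 8
seeded random starts in $[1, 10]\,\mathrm{s^{-1}}$; with the product
constraint $\zeta_1\zeta_2 = c$ active only $\zeta_1$ is free and the
constraint holds exactly in the result. Landing times and target stepping
positions are read from the phase timeline and the foot-position channels,
not co-estimated.

Numerical choices:

* One sample is trimmed at each sub-segment boundary (`trim = 1`): a
  detected heel contact lands on the sample *after* the true event, and
  the straddling sample would otherwise be scored against the wrong task.
* COM position and velocity are smoothed with a zero-phase 2nd-order
  Butterworth low-pass at 6 Hz (the conventional kinematic smoothing
  cutoff for gait data) around a linear trend; without it, sensor noise in
  the regressors biases $\zeta_1$ upward by several percent. Set
  `lowpass_hz = NULL` to fit raw channels — on noiseless data the raw fit
  recovers the generating parameters to machine precision, which is the
  package's exact-model-class test.
* A fit whose optimizer does not report clean convergence is returned with
  `converged = FALSE` rather than as an error.

## The trunk-local frame and turning walks

For walks that change direction, recordings are transformed into a
per-sample local frame at the waist's ground projection with the X axis
along the chest forward heading (low-pass filtered at 1 Hz so step-cycle
oscillation does not leak into the frame). Positions are mapped affinely;
velocities, forces and torques are rotated only. The frame's own motion is
deliberately not differentiated through: subtracting the origin velocity
would zero the forward COM velocity that the balance model needs, whereas
the instantaneous-heading convention keeps the forward speed positive
through a turn. The per-sample origin and yaw are stored in the output, so
the transform is exactly invertible, and a cumulative heading-projected
path length `frame_path_s` is stored alongside. Adding it back to the
local coordinates straightens the walk — a 90° turn becomes a straight
walk in `com_x + frame_path_s` — which is what the identification uses as
its forward axis. On a straight walk this reconstruction equals the global
axis up to a constant, and constant shifts are absorbed exactly by the
anchors, so global- and local-frame fits coincide; the tests assert both
this equivalence and that a 90°-turn fit in the local frame stays within
twice the straight-walk residual.

# The synthetic-data generator

`simulate_walk()` exists so that every stage — detector, ZMP estimator,
identification — can be exercised against known ground truth. Its defaults
are the study conditions used throughout the tests: a 1.65 m / 57 kg
subject, 60 Hz sampling, 0.3 m steps at 0.6 s per step, controller
eigenvalues $\zeta_1 = 4$, $\zeta_2 = 2.16\ \mathrm{s^{-1}}$, COM height
$g/(\zeta_1\zeta_2)$ so the equivalent symmetric frequency matches the
eigenvalue product, and a phase template of LR 10, MSt 20, TSt 20, PSw 12,
ISw 13, MSw 13, TSw 12 percent of the cycle — i.e. the normal 62/38
stance/swing split. Per-leg swing fractions are configurable for
asymmetric gaits.

The COM is integrated with fixed-step 4th-order Runge-Kutta (10 substeps
per 60 Hz frame) under the bilateral law; heel contacts fall on the sample
grid, so task switches never split an integration step. If the commanded
ZMP ever leaves the support excursion bound (default 0.5 m; configurable)
the affected step is reported as infeasible by index.

Plate forces follow a two-peak vertical profile over stance: a rise to
120% body weight with a short plateau around the end of the loading
response, a valley below body weight in mid-stance, a second peak near
terminal stance, and a decay to zero at toe-off. The knots were chosen
once so that the cycle-mean total load over both feet equals body weight
to about 1% (the plateau makes the 120% anchor insensitive to ±1 sample of
detection error). The heel plate carries all load at initial contact, the
toe plate takes over between the end of loading response and the end of
mid-stance — exactly the on/off pattern the force-based detection rules
expect. Pitch torques on the plates are then set so the moment-balance ZMP
of the synthesized wrenches reproduces the simulator's commanded ZMP
exactly before noise; physically they play the role of the ankle torque a
rigid plate cannot resolve into its own load distribution.

Foot, ankle and knee trajectories are keyframed so that every kinematic
detection rule is met at the ground-truth event time with enough signal
slope that threshold crossings stay within one sample: heel-pivot pitch
during loading response, flat foot in mid-stance, heel rise in terminal
stance, a 6 cm mid-swing clearance arc, ankle crossing at the initial- to
mid-swing boundary, and a fast shank sweep through vertical at the mid- to
terminal-swing boundary that then settles inside the alignment tolerance.

Noise is additive Gaussian, seeded: 2 mm on positions, 10 mm/s on
velocities, 2 N on forces, 0.05 N·m on torques. Turning walks are
generated in the straightened path frame and mapped to the world by a
per-sample rigid yaw about the waist, with the heading ramping smoothly
over one gait cycle around the turn step.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: vertical COM excursion (held constant; a model
assumption, not just a simplification), angular-momentum fluctuations
about the COM (the corrected ZMP estimator is tested analytically, not in
the loop), soft-tissue and marker artifacts, non-Gaussian sensor glitches,
slips or missteps, and double-support load-sharing profiles beyond the
template family. Identification results on real recordings will degrade
in proportion to how far those effects take the data from the model class.

# Problem sizes

The test suite and the reproduction script run at desk scale, chosen to
keep every property measurable: six-step walks (about 5 s at 60 Hz, two
steady cycles), single stepping-and-braking trials, eight-step turn walks,
and 20-seed replicates for the noisy recovery medians. Parameter-recovery
tolerances are 2% on noiseless data and 5% in median at the default noise
level; event recovery is within 1 sample noiseless and 3 samples at
default noise.

# Known limitations

* Only the forward axis is modeled and identified; lateral COM motion is
  synthesized for realism but carries no controller semantics.
* The identification assumes the phase timeline is trustworthy; gross
  detection errors shift whole sub-segments rather than single samples.
* The angular-momentum coefficient of the corrected ZMP is exposed as a
  constant with its sign fixed by the defining moment balance (negative);
  it is not co-estimated with the controller.
* Walk-start and walk-stop cycles are intentionally excluded from cycle
  statistics; the detector's output there is reported but degenerate.
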