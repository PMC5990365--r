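---
title: "Event-based mass estimation under visuomotor delay: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based mass estimation under visuomotor delay: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventmass)
```

## The scientific question

When the hand manipulates an object through a tool — here, the handle of a
planar five-bar-linkage manipulandum — the brain must maintain an estimate of
the inertia it is moving. `eventmass` implements a model in which that
estimate is updated *only at collision events*: moments when kinetic energy is
exchanged with the environment and several senses report on the same physical
quantity at once. If the visual feedback is artificially delayed by a time
$\tau$, the visual and proprioceptive measurements of hand velocity at a
collision disagree, and an estimator that insists the perceived kinetic-energy
exchange be consistent across senses must instead revise the *mass* of the
object. The revised mass predicts systematic overshoot (hypermetria) or
undershoot (hypometria) of subsequent blind reaching movements, with the sign
determined by the timing of the hits within the stroke.

The package simulates the full experiment: a delayed virtual pong game played
by a parametric artificial player on the simulated manipulandum, the
estimation of the perceived "mass modifier" from the hit events, and the
open-loop replay of mass-augmented feedforward commands that turns the
modifier into a predicted reach error.

## The manipulandum and the effective mass

The device is a planar five-bar linkage: two actuated base joints on the
x-axis, two proximal links, and two distal links meeting at the handle. The
generalized coordinates are the two actuated angles $q$; the passive distal
angles are eliminated analytically through the loop-closure constraint. The
equations of motion on the horizontal plane (no gravity) are

$$ M(q)\,\ddot q + C(q,\dot q)\,\dot q = u , $$

with $M$ assembled from per-link center-of-mass velocity maps and rotational
inertias plus a lumped handle mass, and $C$ built from Christoffel symbols of
$\partial M/\partial q$ (evaluated by central differences; the quadratic form
$\dot q^\top(\dot M - 2C)\dot q$ vanishes identically by construction).

What the hand feels in a given direction is the *effective endpoint mass*

$$ m_r(q, \theta) = \hat x^\top J^{-\top} M(q)\, J^{-1} \hat x ,
   \qquad \hat x = (\cos\theta, \sin\theta)^\top , $$

the projection of the inertia through the inverse Jacobian onto the unit
velocity vector. It is defined by energy equivalence — the kinetic energy of
the whole linkage equals that of a point mass $m_r$ moving at the handle —
and the package enforces this identity to $10^{-10}$ relative on random
states. $m_r$ is $\pi$-periodic in direction and strongly anisotropic: the
same device feels more than twice as heavy along some directions as others.

**Calibration.** The hardware values of the original device are not public.
The package ships a stand-in parameter set (`base_linkage()`) with link
dimensions typical of planar psychophysics manipulanda, and calibrates two
placement constants (body midline `x_mid` and court distance `y0` in the
robot frame) plus a single mass scale so that the lateral-direction effective
mass is exactly 1.5 kg at the right-court hit position and 1.0 kg at the
left-court hit position — the anisotropy that drives every asymmetry downstream.
The calibration residual is below $10^{-8}$ kg; the frozen constants are the
package defaults (`default_linkage()`, `default_geometry()`) and
`analysis/01_calibrate_linkage.R` reproduces them from scratch. Because the
parameters are a stand-in, absolute joint torques are not comparable to any
particular hardware; effective masses, their ratios, and all derived
quantities are pinned by the calibration.

## The pong game

The game emulates the study's raw material rather than its pixels. A ball
moves inside a 0.2 m square court at 200 Hz with linear speed decay
(friction); it reflects off the side walls, and off the distinguished far
wall where a uniform perturbation on $\pm 0.13$ m/s is added to the
along-wall velocity component. A paddle tied to the simulated hand returns
the ball with the collision law

$$ v^+ = 0.7\, R(\theta)\, v^- + 0.42\, v_{paddle} , $$

where $R(\theta)$ is the reflection matrix about the paddle line. Each
collision also produces a haptic pulse $f = 0.05\,\mathrm{kg}\cdot\Delta
v_{ball}$ lasting 5 ms. Every feedback channel — the visual paddle and ball,
the haptic pulse — is delayed by $\tau$ (80 ms for the frontal court, 120 ms
for the lateral courts). The proprioceptive paddle (the true hand state) is
never delayed.

Constants the study leaves unstated are package choices, recorded in every
session header: serve speed 0.4 m/s, friction 0.05 m/s per second (a few tens
of hits per minute follow), paddle half-length 0.06 m, a 0.5 s re-serve pause
after a miss, a resting (home) paddle position 0.04 m behind the court's near
edge so unanswered balls leave the court instead of being blocked by a
stationary paddle, and a 0.4 s post-collision refractory so the stroke's
follow-through cannot double-hit the ball it has just returned inside the
20 cm court. The last two were added after inspection of the simulated hit
population: without them a large fraction of "hits" were near-zero-velocity
blocks that no attentive player would produce, and they systematically biased
the velocity-mismatch statistics.

## The artificial player

The player is an explicit modelling choice (no human data enter the package).
It watches the *delayed* visual ball, advances it by its learned delay
compensation (fully adapted by default; an exponential approach with
`adaptation_rate` is available), anticipates the far-wall bounce — whose
perturbation is transverse, so arrival *timing* at the interception line is
predictable while the *aim* carries the unpredicted noise — and plans a
reciprocal minimum-jerk stroke through the predicted interception point.

The key parameter is `timing_offset` ($\delta$): the stroke is placed so the
contact lands $\tau/2 + \delta$ after the stroke's velocity peak. Because the
visual speed profile is the proprioceptive one shifted by $\tau$, the two
speeds cross exactly half a delay after the peak; $\delta$ is therefore
measured *from the crossing*, so that its sign directly selects the hit-timing
category for any delay (and coincides with "offset from the peak" when
$\tau = 0$):

* $\delta < 0$ — hits in the accelerating phase, visual slower than
  proprioceptive, negative mass modifier;
* $\delta = 0$ — hits at the crossing, equal speeds, zero modifier;
* $\delta > 0$ — hits in the decelerating phase, visual faster, positive
  modifier.

Per-stroke timing jitter (SD 20 ms) and aim jitter (SD 1 cm) emulate human
variability; they are what gives the per-hit mass samples non-zero variance,
which the fusion stage needs.

## Estimating the mass modifier

From the trailing window of a session (five minutes by default — the player
is statistically stationary, so six-minute sessions suffice and are what the
tests and drivers simulate), the recorded hand velocity is smoothed with a
fifth-order Butterworth low-pass at 20 Hz applied forward-backward. The
zero-phase direction choice keeps hit-time velocities unbiased in time; an
odd-reflection pad suppresses the edge transients of the filter's
zero-initial-condition implementation. Per hit at time $t$:

* proprioceptive speed $v_p$ = smoothed hand speed at $t$, projected on the
  instantaneous direction of motion;
* visual speed $v_v$ = smoothed hand velocity at $t - \tau$, projected on the
  same direction (the delayed display replays the hand's own past);
* reference mass $m_r$ = effective mass at the hit configuration along that
  direction.

The per-modality effective masses are $m_v = m_r$ and
$m_p = m_r\, v_v^2/v_p^2$ — the unique proprioceptive mass for which the
kinetic-energy estimate is the same through both senses. Hits with
$v_p < 0.02$ m/s are rejected before the division (the 10-SD outlier rule
alone does not bound the ratio), and hits whose $m_p$ deviates from the mean
$m_v$ by more than ten SDs of $m_v$ are removed. Maximum-likelihood cue
combination then weights the two channels by their reciprocal sample
variances over hits:

$$ E(m) = \frac{1/\sigma_v^2}{1/\sigma_v^2 + 1/\sigma_p^2}\, \bar m_v
        + \frac{1/\sigma_p^2}{1/\sigma_v^2 + 1/\sigma_p^2}\, \bar m_p ,
   \qquad \hat m = E(m) - m_r . $$

The variances are empirical per-session sample variances (the study does not
state how they are obtained); with them, fusion necessarily *shrinks* the
session modifier relative to the per-hit closed form
$\hat m_{hit} = m_r (v_v^2 - v_p^2)/v_p^2$: at a constant velocity ratio $r$
the fused modifier converges to $w_p\, m_r (r^2 - 1)$ with
$w_p = 1/(1 + r^4)$, not to $m_r(r^2-1)$ itself. The per-hit form satisfies
the exact energy bookkeeping $\tfrac12 (m_r + \hat m_{hit}) v_p^2 = \tfrac12
m_r v_v^2$; the tests assert both the exact per-hit identity and the
algebraic shrinkage identity $\hat m = w_p(\bar m_p - \bar m_v)$ of the fused
estimator. Sign, monotonicity in the velocity ratio, proportionality to
$m_r$, and every ordering used downstream are unaffected by the shrinkage.

## Predicting blind reaches

A reach is planned as a straight minimum-jerk trajectory (quintic profile,
zero boundary velocity and acceleration, peak speed $\tfrac{15}{8} D/T$) to
targets 0.14 m from the start; joint-space derivatives are obtained
analytically through the Jacobian and its directional derivative rather than
by differencing sampled angles, which keeps the zero-modifier round trip
below $10^{-4}$ m. Inverse dynamics on the *augmented* model — the mass
modifier added as a point mass at the handle, the only placement that shifts
the effective mass by exactly $\hat m$ in every configuration and direction —
produce feedforward torques that are then replayed open-loop on the true
model (adaptive Runge–Kutta, relative tolerance $10^{-8}$, resampled at
200 Hz). There is no feedback and no stopping controller: the reaches are
blind by construction. The signed error along the start-to-target direction
at the end of the planned duration is the extent error (positive =
hypermetria); the extent at maximal excursion is also reported since the
study does not say at which point extent was read. Reach duration defaults to
0.6 s (unprinted in the study); the sign law is verified across durations
0.4–1.0 s in the test suite. The augmented handle mass may go negative for
negative modifiers — it describes a percept, not hardware — but a modifier
that drives the augmented inertia indefinite (at or below minus the effective
mass) is refused as nonphysical.

Because the right-court hit region is calibrated to $m_r = 1.5$ kg and the
left to $1.0$ kg, and the modifier is proportional to $m_r$ at a fixed
velocity ratio, identical cohorts playing in the two courts acquire different
modifiers and different hypermetria — the central asymmetry the cohort
replications reproduce.

## Cohort replications and their scale

`run_group_experiment()` replicates the reaching–pong–reaching design per
synthetic subject: draw $\delta$ from the cohort distribution, play a
session, estimate $\hat m$ in the trailing window, and run the three-target
battery before (modifier zero, plus Gaussian endpoint noise of SD 5 mm
emulating baseline blind-reach variability) and after (estimated modifier).
Problem sizes in the shipped drivers and tests — cohorts of 4–6 subjects,
sessions of 4–6 minutes with 3–5 minute analysis windows — were chosen as the
smallest at which the ordering statistics are stable across seeds; the study
design (8 subjects, 40-minute adaptation) is the default where a single
number must be fixed (`cohort_spec(n_subjects = 8)`), and all sizes are
arguments. No human-subject statistics (t-tests, ANOVAs, the printed
percentages) are reimplemented: group comparisons are reported as ordered
means, and the nested-predictor comparison uses the variance-explained
decomposition $1 - SS_{res}/SS_{tot}$.

The alternative-explanation metrics are included: the visuomotor gain (arm
path length over visual-paddle path length from movement initiation — a 5 %
of-peak-speed threshold — to contact; equal to $T/(T-\tau)$ for uniform
motion), and the spatial vision–proprioception mismatch at hits
($\approx |v|\tau$). Both are *identical across the two lateral courts* by
construction of the game, which is exactly why they cannot explain a
court-dependent aftereffect, while the effective-mass account can.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the estimator assumes:
velocity-matched visual/proprioceptive pairs at hits, hit-timing control via
$\delta$, configuration and direction spread from aim noise, far-wall bounce
noise, and seeded determinism (identical configuration and seed give
byte-identical logs). It does not model: motor noise or feedback corrections
inside a stroke, within-session learning of the modifier (the player is
already adapted; only the end-of-adaptation window is analysed), joint
friction or motor dynamics, fatigue, or any trial-to-trial carryover in the
reaches. Passing tests therefore demonstrate the internal consistency of the
model chain — collision physics, energy bookkeeping, estimator algebra,
dynamics round trips, and the qualitative orderings (hit-timing taxonomy,
court asymmetry, nested variance) — not that human subjects behave this way;
the human-cohort percentages and significance tests from the original study
are out of scope because the subject data are unavailable.

## Numerical choices

* Closure branch: elbow-out working mode, fixed over the whole workspace;
  inverse kinematics never switches branch mid-trajectory. Closure failures
  and near-singular Jacobians (condition number above $10^8$) raise explicit
  errors.
* $\partial M/\partial q$ by central differences with step $10^{-6}$ rad;
  the skew-symmetry property of $\dot M - 2C$ then holds exactly for the
  matching $\dot M$, and passive simulations conserve energy to $10^{-6}$
  relative over the test horizon.
* Integrator: `deSolve` ode45, rtol $10^{-8}$, atol $10^{-10}$, output on
  the 200 Hz recording grid; halving the tolerance moves reach endpoints by
  less than $10^{-6}$ m.
* Contact detection at the 5 ms game step: first crossing of the ball path
  with the moving paddle plane wins, with sub-step interpolation of the
  crossing time; the paddle is a fixed-orientation segment (horizontal for
  the frontal court, vertical for the lateral courts).
* Ties and degenerate inputs: a zero-variance fusion channel takes weight 1
  (both zero is an error); a constant visual-mass sample (zero SD) retains
  only exact matches in the outlier filter; hits earlier than one delay after
  session start are skipped; a friction-killed ball is re-served.

## Reproducing the analyses

The numbered drivers under `analysis/` run the whole workflow in order:
calibration (01), effective-mass polar maps (02), example sessions per group
(03), mass estimation on their logs (04), the modifier-to-extent sweep (05),
and the cohort replications with the variance decomposition (06). Outputs are
plain CSV/JSON under `results/`. `scripts/acceptance.R` recomputes the
collision-law ratios and the bounce-noise support from scratch and writes
them as JSON.
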