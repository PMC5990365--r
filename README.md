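# eventmass

Event-based mass estimation and blind-reach prediction under visuomotor
delay, on a simulated five-bar-linkage manipulandum.

## The problem

How does the sensorimotor system keep track of the inertia of an object it is
manipulating? `eventmass` implements and tests a model in which the mass
estimate is revised **only at collision events** — moments of kinetic-energy
exchange at which vision and proprioception report on the same quantity
simultaneously — under the constraint that the perceived energy exchange stay
invariant across the senses. When the visual feedback of a virtual pong game
is delayed by τ, the visual paddle velocity at a hit is the proprioceptive
velocity from τ earlier, the two senses disagree, and the constraint forces a
perceptual **mass modifier** m̂ onto the internal model of the device:

- effective endpoint mass (what the hand feels moving in direction θ at
  configuration q):  m_r = x̂ᵀ J⁻ᵀ M(q) J⁻¹ x̂,  x̂ = (cos θ, sin θ)ᵀ — the
  projection of the generalized inertia through the inverse Jacobian, defined
  by ½ q̇ᵀ M q̇ = ½ m_r |ẋ|²;
- energy-consistent per-modality masses at a hit:  m_v = m_r  and
  m_p = m_r · v_v²/v_p²;
- maximum-likelihood cue combination:  E(m) = w_v m̄_v + w_p m̄_p with
  inverse-variance weights, and  **m̂ = E(m) − m_r**;
- prediction: inverse-dynamics torques computed on the m̂-augmented model and
  replayed open-loop on the true model over- or undershoot the target —
  hypermetria for m̂ > 0, hypometria for m̂ < 0.

The package is aimed at computational sensorimotor-control researchers: it
contains the full five-bar kinematics and Euler–Lagrange dynamics (with the
direction-dependent effective mass), an event-driven delayed-pong simulator
with a parametric artificial player, the estimation chain (20 Hz zero-phase
Butterworth smoothing, 10-SD outlier rejection, ML fusion), minimum-jerk
reach prediction, and cohort-level replications of the three experimental
groups (frontal pong, lateral-right, lateral-left).

## Worked example

Simulate six minutes of delayed lateral pong played by an agent that hits the
ball 40 ms into the decelerating phase of its stroke, estimate the mass
modifier from the last five minutes, and predict a blind reach:

```r
library(eventmass)

config  <- pong_config("lateral_right")        # 0.2 m court, tau = 120 ms
player  <- player_model(timing_offset = 0.04)  # hits after the speed crossing
session <- run_pong_session(config, player, duration = 360, seed = 1)
session
#> Pong session: lateral_right court, tau = 120 ms, 6.0 min
#>   151 hits (25, 22, 26, 26, 27, 25 per minute), 220 misses, 151 strokes

est <- session_mass_estimate(default_linkage(), session, window_min = 5)
est
#> Mass estimate over 125 hits
#>   visual:        mean 1.584 kg, var 0.1879 (weight 0.779)
#>   proprioceptive: mean 2.295 kg, var 0.6643 (weight 0.221)
#>   fused E(m) = 1.741 kg, mass modifier = +0.157 kg

outcome <- predict_reach(default_linkage(), est$m_hat,
                         group_geometry("LP_R")$targets[[2]])
round(1000 * outcome$extent_error, 1)
#> [1] 27.1
```

Reading the numbers: the visual channel sees the true effective mass of the
right-court hit region (≈ 1.5 kg, the calibrated value); the proprioceptive
channel, forced to match the visually estimated kinetic energy with the
faster visual velocities of late hits, infers a heavier paddle (≈ 2.3 kg);
inverse-variance fusion lands at 1.74 kg, i.e. a mass modifier of +0.16 kg.
Planning a 0.14 m blind reach with that extra perceived mass and executing
the torques on the real device overshoots the target by ≈ 27 mm — hypermetria.
An agent hitting before the velocity crossing (`timing_offset < 0`) produces
the opposite sign throughout.

The numbered scripts under `analysis/` run the full workflow — linkage
calibration, effective-mass polar maps, per-group sessions, mass estimates,
the modifier→extent sweep, and the cohort replications (hit-timing taxonomy,
right/left court asymmetry, alternative-explanation metrics, and the
group-mean vs individual-modifier variance decomposition) — writing plain
CSV/JSON under `results/`.

## Package layout

- `R/linkage.R`, `R/kinematics.R`, `R/dynamics.R` — five-bar model: closed
  form kinematics, Jacobian, inertia/Coriolis, effective mass, inverse and
  forward dynamics, calibration.
- `R/pong.R`, `R/session_io.R` — the delayed pong simulator, artificial
  player, and CSV/JSON session store.
- `R/estimation.R` — filtering, hit-velocity extraction, per-modality masses,
  outlier rejection, ML fusion, mass modifier.
- `R/reach.R` — minimum-jerk plans, model augmentation, blind-reach outcomes.
- `R/pipeline.R` — group geometry, cohort replications, variance explained,
  timing/gain/mismatch session metrics.
- `vignettes/event-based-mass-estimation.Rmd` — the model, its assumptions,
  parameter choices, and known limitations.
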