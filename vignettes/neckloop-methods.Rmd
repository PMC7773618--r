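---
title: "Methods: closed-loop reflexive neck-muscle simulation and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop reflexive neck-muscle simulation and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckloop)
```

## The model

`neckloop` couples three components in a fixed-step loop:

**Plant.** The head–neck complex is a planar (sagittal) chain of eight
rigid links riding on a kinematically prescribed T1 base: seven cervical
segments and the head. Each joint carries a linear rotational spring whose
rest position is the configured initial alignment (a mild lordosis by
default) and a viscous damper; gravity acts on every segment. The
equations of motion are assembled from link Jacobians (mass matrix plus
velocity, gravity, spring/damper and muscle generalized forces) and
integrated with fixed-step RK4. T1 motion enters as a moving base — a
constraint, not a force — so the boundary channels are reproduced exactly.

**Muscles.** Eight line-of-action actuators span 2–8 joints with via
points: four extensor groups behind the column and four exactly mirrored
flexor groups in front, standing in for the full bilateral fascicle
arrangement of a finite-element neck. Element force is
`F = PCSA · σmax · (Na·fv(v)·fl(l) + fpe(l))`, clamped at zero because
muscles only pull. The force–length curve is a Gaussian of width 0.56, the
force–velocity curve is hyperbolic in shortening and saturates at 1.5 in
lengthening, and the parallel-elastic curve is exponential above the slack
length; every constant sits in `muscle_mechanics()`. Optimal lengths are
taken as the path lengths in the initial alignment and slack equals
optimal, so the baseline posture carries no passive muscle force and the
mirrored 5% co-contraction tensions cancel — the tone balances the head
statically, as closed-loop neck models require.

**Controller.** The reflex is angular-positioned feedback: the orientation
of the vector from the T1 vertebral-body centre to the head centre of
gravity, measured from vertical (positive in extension), is compared with
the reference captured at the end of gravity settling. The error is
delayed by `Tnd` (linear interpolation in a sample buffer; zero during
warm-up), differentiated by a backward difference *after* the delay
(the alternative order is available via `rate_before_delay`), scaled by
`u = (Kp·e + Kd·ė)/100` with `ė` in rad/ms, and distributed by a
half-wave-rectified cosine spatial-tuning pattern: positive error (head
fallen rearward) recruits the flexors, negative error the extensors, each
muscle in proportion to the cosine of the angle between its preferred
direction and the demand. The excitation then passes the Winters–Stark
two-stage cascade (`Tne`, then `Tna,a`/`Tna,d` selected by the sign of
`Ne − Na`; both stages advanced by their exact exponential solution each
step) and is clamped to `[0.05, 1]`. The floor doubles as the relaxed
co-contraction level: a passive run is identical to a zero-gain run.

## Parameters that matter

| Parameter | Unit | Default | Range | Meaning |
|---|---|---|---|---|
| `kp` | %contraction/rad | 0.601 | 0.601–40 | proportional reflex gain |
| `kd` | %contraction/(rad/ms) | 412.62 | 5–412.62 | derivative reflex gain |
| `tnd` | ms | 15 | 3.5–20 | neural transmission/processing delay |
| `tna_a` | ms | 10 | 5–15 | muscle activation time |
| `tna_d` | ms | 40 | 20–60 | muscle deactivation time |
| `tne` | ms | 35 | 20–50 | neural excitation time |
| co-contraction | – | 0.05 | fixed | activation floor / relaxed tone |

With `ė` expressed in rad/ms the derivative term contributes at most a few
percent activation anywhere in the `kd` range; the proportional path
dominates. This matches the calibration experience that the derivative
gain is the least sensitive parameter and routinely converges to its
lower bound.

The plant constants (link lengths 17 mm, vertebral mass 0.2 kg and
rotational inertia 5×10⁻⁴ kg·m² about the joint — soft-tissue-inclusive
effective values — head 3.6 kg / 0.029 kg·m², joint stiffness
40 N·m/rad, damping 0.35 N·m·s/rad, head CG 55 mm above the C1 joint) are
surrogate configuration, not anatomical measurements. They were chosen
once so that (i) the bare column has a static equilibrium under gravity
with a head-CG sag near 1 cm, (ii) the passive peak head excursion under
the default pulse is of volunteer order (≈7 cm relative to T1, ≈0.6 rad
extension), and (iii) the fastest overdamped joint modes remain inside the
RK4 stability region at the default step. The inertia floor matters: with
near-zero vertebral inertia the damped modes are faster than any explicit
fixed-step integrator at 0.5 ms can follow.

## Numerical choices

* **Integration**: RK4 at `dt = 0.5 ms` (config). Halving `dt` moves the
  peak head excursion by ~10⁻⁵ %; an energy audit of the undamped,
  unactuated, gravity-free chain drifts by less than 0.1% over 400 ms.
* **Settling**: the protocol's 100 ms gravity settling is solved
  statically — an overdamped relaxation into the equilibrium well
  containing the initial alignment followed by a Newton polish, verified
  by residual joint accelerations. Plain Newton is avoided because the
  axially loaded column has multiple static branches and Newton happily
  jumps between them. The settled posture is memoized; a calibration run
  settles once, not once per simulation.
* **Controller sampling** runs at the integrator step with zero-order-hold
  muscle drives inside the RK4 stages.
* **Delay**: linear interpolation in the error buffer; exact on ramps,
  O(dt²) on band-limited signals.
* **Degenerate inputs**: coincident head/T1 points, non-positive time
  constants, non-finite states and zero-length path segments are rejected
  with diagnostics; simulations that leave `|q| ≤ π` are aborted with the
  violating step, and optimizers replace such evaluations with a finite
  penalty (10× the worst feasible objective seen).

## Output frame

Head displacement channels are reported relative to the moving T1/sled
base by default. With the sled displacement folded into T1, ground-fixed
head x-displacement is dominated by rigid transport (~0.1 m of monotone
forward motion) on which the muscle effect is invisible — indeed active
muscles *increase* it by coupling the head to the torso earlier. The
retraction/rebound excursion that reflex activity reduces, and that
volunteer corridors describe, is the base-relative motion, so that is the
default; `frame = "lab"` provides the ground-fixed alternative.

## Metrics

The calibration objective is an area-based curve-mapping discrepancy:
both curves are resampled to a common grid, time is normalized by the
window length and values by the mean of the two curves' ranges (making
the score symmetric and invariant to a common change of measurement
units), and the discrepancy is the area enclosed between the normalized
polylines. The evaluation rating is CORA-style: a corridor sub-score with
inner/outer half-widths of 5% and 50% of the target's peak magnitude
(linear fall-off between them) combined 50/50 with equally weighted
shape/size/phase correlation sub-scores (best-lag cross-correlation,
absolute-area ratio, normalized best lag). The sub-weights and corridor
construction are configuration: the rating is *CORA-style*, not
bit-compatible with the closed-source CORAplus tool, and published CORA
tables for FE models against proprietary volunteer data are out of reach
by construction.

## Calibration

`optimize_srsm()` is a sequential response surface method with domain
reduction: per iteration a maximin Latin-hypercube pool (10× the point
count) is drawn in the trust region, a greedy D-optimal subset of 11
points including the region centre is simulated, a linear polynomial is
fitted by least squares and minimized in-region by simulated annealing
plus an L-BFGS-B polish, and the region is re-centred on the predicted
optimum and contracted (factor 0.4 at zero move growing to 1 for
full-region moves, an extra 0.6 on per-coordinate oscillation). Stopping:
10 iterations, or design change and objective change both below 1% —
design change measured against the full bounds range. On 6-D convex test
bowls the recovered minimum lands well within 1–2% of the bounds range.
`optimize_ga()` is a real-coded GA (tournament size 6, blend crossover
α = 0.3, bounded Gaussian mutation annealing from 10% of range, one
elite) with one verification evaluation of the elite; it serves as the
strategy cross-check, and `chained_validation()` restarts the metamodel
search from the GA optimum with only `kp`/`kd` free.

Linear correlations between all sampled parameter vectors are reported
with the conventional categories weak (|r| ≤ 0.29), medium (0.30–0.49)
and strong (0.50–1.00), applied to |r| rounded to two decimals; frozen
parameters yield undefined entries.

## Synthetic data, and what passing tests do not show

`generate_pulse()` produces a C²-smooth low-severity rear-impact boundary:
quintic-smoothstep sled and T1 x-ramps (peak 0.12 m and 0.015 m at
180 ms, ≈2 g) and sin⁴ bumps for T1 z (−8 mm) and y-rotation (0.10 rad)
returning to zero within 300 ms — zero initial value, rate and
acceleration by construction. `generate_surrogate_target()` runs the
closed loop with known true parameters and adds seeded Gaussian noise
(fraction of channel range) with an optional low-pass, emulating smooth
averaged volunteer curves. With zero noise the target is exactly a model
output, which closes the loop: the objective at the truth is zero to
machine precision for all four objective presets.

Two deliberate choices in the recovery experiments deserve a note. First,
the default fixture parameters are the calibration initial values
(`kp = 0.601`, …); at that gain the commanded activation never leaves the
5% floor, so those fixtures exercise the pipeline but cannot identify the
time constants. Recovery experiments therefore use an *informative* truth
(`kp = 35`, `kd = 200`, `tnd = 5`, `tna_a = 5`, `tna_d = 25`, `tne = 20`).
Second, the data identify the total reflex latency — delay plus cascade
lag — rather than each constant separately; with mid-range lag constants
an optimizer will happily trade `tnd` down while trading `tne` up at
essentially unchanged objective. Placing the truth's lag constants at
their lower bounds blocks that trade, making `tnd` itself recoverable.
Both facts are properties of any such controller calibration, not of this
implementation.

What the synthetic surrogates do **not** emulate: inter-subject
variability, instrumentation artefacts, head-restraint contact, 3-D
coupling, and the real volunteers' curve shapes. Passing the recovery and
concordance tests shows the estimation machinery is self-consistent and
the optimizers competent at the study's budgets — not that the surrogate
plant reproduces any particular human dataset.

## Problem sizes used in the shipped experiments

Simulations run 300 ms events (plus static settling) at `dt = 0.5 ms`
with 1 ms output sampling. The calibration experiments use the study
budgets — 11 points × ≤10 iterations for the metamodel search and
30 × 10 for the GA — with 5 noisy targets in the recovery experiment.
The end-to-end replay tests in the unit suite run the same pipeline at
reduced optimizer budgets (6–9 points, 2–3 iterations); the acceptance
script and acceptance tests run the full budgets.

## Known limitations

* The plant is planar with lumped joint compliance; no tissue-level
  response, no contact, no lateral or axial degrees of freedom.
* The spatial tuning pattern is a two-direction cosine in the sagittal
  plane; the full directional recruitment map of a 3-D neck collapses to
  flexor/extensor selection here.
* A single vector angle cannot control individual vertebral rotations:
  calibrating to cervical channels alone leaves the controller weakly
  authoritative over them — an inherent limit of single-vector feedback.
* `Kd` in %contraction/(rad/ms) has little authority across its whole
  range; its recovery is not expected to be tight, and the package does
  not pretend otherwise.
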