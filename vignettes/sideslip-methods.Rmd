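---
title: "Modeling roll-based sideslip maneuvers in hawkmoth flight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling roll-based sideslip maneuvers in hawkmoth flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothslip)
```

## The scientific question

Hovering hawkmoths (*Manduca sexta*) can translate directly sideways — a
"sideslip" — without turning. Two mechanisms could produce the lateral
force: direct lateral force from left–right timing asymmetries in wing
pitch rotation (as described in fruit flies), or a whole-body roll that
reorients the stroke-averaged force vector, the way a banking aircraft
turns. `mothslip` implements, end to end, the analysis that
discriminates between these hypotheses on digitized flight video — and,
because no raw videographic data are publicly deposited, a physics-based
synthetic-data generator that stands in for the animal.

The package's statistical core tests a constant, dorsally directed
force model. If the moth produces a stroke-averaged force equal to body
weight along its dorsal axis and rolls by an angle $\beta$ (measured
absolute to the horizontal plane, positive when the right wing base
drops), then in a +z-down global frame:

$$\ddot{y} = K_{\ddot y \beta}\, g \sin\beta + K_{\ddot y \dot y}\,\dot y
  + K_{\ddot y \Phi}\,\mathrm{sgn}(\beta)\,\bar\Phi_{pc}
  + K_{\ddot y \theta}\,\mathrm{sgn}(\beta)\,\bar\theta_{pc}$$

$$\ddot{z} = K_{\ddot z \beta}\, g (1 - \cos\beta) + K_{\ddot z \dot z}\,\dot z
  + K_{\ddot z \Phi}\,\bar\Phi_{pc} + K_{\ddot z \theta}\,\bar\theta_{pc}$$

$$\dot\beta = K_{\dot\beta\alpha}\,\alpha_{LR}
  + K_{\dot\beta\Phi}\,\Phi_{pLR} + K_{\dot\beta\theta}\,\theta_{pLR}
  + K_{\dot\beta\dot y}\,\dot y$$

where $\bar\Phi_{pc}$ and $\bar\theta_{pc}$ are bilateral sweep and
elevation amplitudes centered on the whole-dataset mean, and the $LR$
subscript denotes left-minus-right differences. Under the roll-based
hypothesis $K_{\ddot y \beta}$ and $K_{\ddot z \beta}$ should both be
close to one; velocity terms should carry negative (damping) signs; and
the wing-pitch asymmetry $\alpha_{LR}$ should be the dominant positive
driver of roll *velocity* — not roll *acceleration* — because roll is
heavily damped and therefore behaves as a first-order system on the
halfstroke timescale. The roll-velocity model carries no intercept: a
stably hovering moth has no asymmetry and no damping torque, so a
significant intercept would indicate a mis-specified model.

## The blade-element simulator

`sim_config()` and `integrate_flight()` implement a quasi-steady
blade-element model of a flapping moth with three free body degrees of
freedom: lateral position $y$, vertical position $z$ and roll $\beta$.
Fore–aft translation, yaw and pitch are frozen; the sideslip models
involve only the free three, and yaw control is a separate problem.
Each wing pair (forewing and hindwing treated as one blade) is divided
into spanwise elements; the relative air velocity at each element sums
the flapping velocity, the body translational velocity, and the
roll-rate-induced velocity $\dot\beta \, r$ at that span station. That
last coupling is what produces flapping counter-torque (FCT): an
imposed roll adds airspeed to the wing rolling into the flow and
subtracts it from the other, generating an opposing torque without any
sensory feedback.

Three quasi-steady force terms are summed per element:

* translational lift and drag with
  $C_L = A_L \sin 2\alpha_e$ and $C_D = C_{D0} + B_D (1 - \cos
  2\alpha_e)$ of the signed effective angle of attack $\alpha_e$,
* a rotational (Kramer) term
  $F_{rot} = C_{rot}\,\rho\,c^2\,\omega_{pitch}\,v$ per unit span with
  $C_{rot} = \pi(0.75 - \hat x_0)$,
* an added-mass reaction $m_a = \rho \pi c^2 / 4$ per unit span acting
  against the flapping acceleration normal to the wing surface (the
  body-acceleration contribution to added mass is neglected, which
  keeps the equations of motion explicit).

Defaults — $A_L = 1.8$, $C_{D0} = 0.1$, $B_D = 1.7$, $\hat x_0 = 0.25$,
a 2 g moth with 5 cm wings, elliptic chord with 1.8 cm mean, flapping
at 26 Hz — were calibrated once, against a single plausibility
criterion: hover trim (weight support at rest) must occur at a
peak-to-peak sweep amplitude near 110–120°, the hovering amplitude of a
real hawkmoth. All constants are user-facing fields of `sim_config()`.
CGS units (cm, g, s) are used throughout, with $g = 980.665$ cm/s²;
angles are degrees at every interface and become radians only inside
trigonometric kernels.

Two geometric choices matter for the passive dynamics and deserve
explanation. First, the wing bases sit 1.2 cm dorsal to the center of
mass, so lateral drag on the flapping wings produces a restoring roll
moment during sideslip. Second, the default mean elevation angle is
16°: the wings are slightly coned above the horizontal, giving the
stroke plane an effective dihedral. With a flat stroke plane and
wing bases at the center of mass, the blade-element model's
sideslip-to-roll coupling comes out *destabilizing* — lateral velocity
rolls the moth further into the slip and the coupled lateral/roll
system spirals away. The coned, high-base configuration yields the
stabilizing coupling ($K_{\dot\beta\dot y} < 0$) that the observed
moths display, and is anatomically reasonable. This is a genuine
modeling degree of freedom, fixed once from the stability requirement
and not revisited.

Wing kinematics are commanded per wing (`wing_command()`): cosine sweep
and elevation waveforms with mean, peak-to-peak amplitude and phase,
and a wing-pitch command that transitions between the downstroke and
upstroke midstroke pitch through a cosine-smoothed square wave whose
reversal occupies 10% of the halfstroke by default. Only midstroke
pitch is scientifically interpreted; the reversal shape is a numerical
convenience and its fraction is configurable.

Integration is fixed-step classical Runge–Kutta at 64 steps per
wingbeat (at least 50 are enforced), which resolves the fastest
dynamics — the sub-wingbeat roll response — with ample margin and makes
every run bit-reproducible. States exceeding physical bounds (3 ×
10⁴ cm/s, 10⁵ deg/s) abort with a diagnostic rather than silently
producing garbage.

`damping_probe()` measures passive damping by impulsively perturbing
one axis of a trimmed, symmetrically flapping moth and regressing the
wingbeat-to-wingbeat velocity derivative on velocity. Roll damping is
so strong that the decay completes within roughly a wingbeat, at the
resolution limit of wingbeat averaging; lateral and vertical decays
span many wingbeats and are well resolved. Because the free dynamics
couple roll and lateral motion, the probe can optionally freeze the
other axes (`isolate = TRUE`) to measure single-axis damping; the
package's tests cross-check the isolated lateral decay rate against
the damping coefficient fitted by the regression pipeline on the same
trajectory.

## The synthetic observables

The study's raw observable was not a trajectory but hand-digitized 3D
landmarks: eight points (scutum, abdomen tip, both wing bases, both
forewing tips, both hindwing tips) at four visually identified stroke
phases per wingbeat — end-downstroke, end-upstroke, mid-downstroke,
mid-upstroke. `landmarks_from_trajectory()` reproduces exactly this
sampling: phase times come from the extrema and mean crossings of the
commanded sweep waveform (the deterministic analogue of visual phase
identification), the eight landmarks are placed from a rigid body
template posed by $(y, z, \beta)$ plus the commanded wing vectors,
isotropic Gaussian noise is added in the global frame, and hindwing
tips are dropped at a configurable rate (they were occasionally
invisible to the digitizers). The default noise of 0.05 cm is an
order-of-magnitude choice consistent with sub-pixel triangulation
error over a ~70 cm filming volume; digitization precision per
landmark was never reported, only calibration residuals of roughly
0.1–0.15 px.

The template is built so that the centroid of scutum and wing bases
and the abdomen tip both lie on the body x-axis; the body-axis
construction used downstream then recovers the commanded pose exactly,
and the noiseless round trip (commanded angles in, extracted angles
out, to below 10⁻⁶ degree) is a standing test. The rendered chord
landmark is chosen in the plane perpendicular to the span so that its
body x/z projection makes exactly the commanded pitch angle — the same
convention the kinematics module measures — so wing pitch also round
trips exactly at every phase.

What the generator does *not* emulate: digitization bias correlated
across frames, lens distortion, wing flexion and camber (the chord is
rigid), abdominal articulation, and yaw/pitch wander. Passing tests on
synthetic data therefore demonstrate that the analysis chain is
correct and that the physics of the blade-element moth supports the
roll-based mechanism; they cannot certify the digitizing protocol of
any particular laboratory.

For end-to-end tests of the camera chain, `make_camera()`,
`project_to_cameras()`, `calibrate_dlt()`, `triangulate()` and
`wand_diagnostics()` implement the standard 11-coefficient direct
linear transformation. Calibration here requires known 3D control
points; self-calibrating wand bundle adjustment (done in the original
workflow by external software) is out of scope, and the synthetic
two-LED wand — 68.5 mm between LEDs, waved smoothly through the
volume — serves as a reconstruction diagnostic only.

## From landmarks to the stroke table

`frame_kinematics()` computes body pose per frame: the body x-axis
from abdomen tip to the centroid of scutum and wing bases, the y-axis
from the wing-base line orthonormalized by Gram–Schmidt, and Euler
angles by the intrinsic yaw–pitch–roll (z-y-x) decomposition. This
sequence is a documented choice: it is the decomposition consistent
with a roll "absolute to the horizontal plane" and with a modified
global reference frame (MGRF) built by rotating the global frame in
yaw only, keeping z vertical. Body position and its derivatives live
in the MGRF; wing angles live in the full body frame (BRF); roll is
global.

Derivatives are deliberately *not* frame-to-frame. Position and
orientation change enormously within a wingbeat for reasons that have
nothing to do with the maneuver; differencing like-phase samples one
wingbeat apart annihilates any signal with period exactly one wingbeat
(a property the tests verify analytically) and the four phase-specific
estimates are averaged per wingbeat. Second derivatives apply the same
stencil to the first derivatives. The roll angle entering the
regression rows is likewise the wingbeat-mean of its four frames: the
responses are wingbeat-filtered quantities, and pairing them with a
single noisy instantaneous roll sample would attenuate the fitted
coefficients through errors-in-variables bias (wing-base separation is
about 1 cm, so 0.05 cm landmark noise is several degrees of
instantaneous roll noise).

`build_stroke_table()` produces one row per halfstroke: midstroke
angles per wing, halfstroke amplitudes (the angle between body-frame
forewing vectors at consecutive opposite endstrokes, with sweep and
elevation amplitudes from the corresponding plane projections)
inserted at their midstroke points, left-minus-right asymmetries, pair
means, centered columns (whole-dataset mean subtracted, recorded in a
JSON sidecar), the ipsilateral-wing drag proxy $|v|\sin\theta_i$, and
the wingbeat-scale body state. Maneuvers are labeled as maximal runs
of constant-sign lateral acceleration lasting at least 0.077 s (about
two wingbeats). When the hindwing tip is missing, wing pitch falls
back to the forewing-vector normal in the x/z plane and the row is
flagged rather than dropped.

## Model fitting and selection

`fit_linear()` is ordinary least squares with the intercept convention
of each response; `fit_mixed_random_intercept()` fits a Gaussian
random-intercept model by REML (via `lme4`), flags singular
(zero-variance) fits instead of failing, computes the conditional
r² as the fixed-plus-random share of total variance, and approximates
fixed-effect p-values with a residual-degrees-of-freedom t
distribution. AICc is computed as
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting every estimated
parameter, variance components included — a documented choice, since
the variance-counting convention is ambiguous in the source analyses.
For mixed fits the REML criterion is used as $\ell$.

`cascade_select()` implements the cascade comparison: terms ordered by
full-model significance (ties broken by larger |t|), grown one at a
time with acceptance only on AICc improvement, one-step recursion that
re-tests the lone exclusion of the previously confirmed term, then
random-intercept variants of the surviving specification. An
exhaustive minimum-AICc enumeration over all subsets
(`exhaustive_select()`) serves as the independent reference in tests;
on small candidate sets the cascade must agree with it at least 90% of
the time. Contribution percentages weight each coefficient by the mean
absolute value of its predictor; damping time constants are
$-1/K$ for each fitted collinear-velocity coefficient, with half-life
$\ln 2 \cdot \tau$.

## The synthetic study conditions

`run_pipeline()` fixes the study conditions: 4 moths (morphology
jittered a few percent, each trimmed to hover), 3 sideslip trials per
moth — 12 maneuvers, comfortably above the 10 the headline test
requires and close to the 19 of the original dataset — rendered at
0.05 cm landmark noise with 2% missing hindwing tips, yielding on the
order of 200 halfstroke rows. Each trial commands hover, a roll pulse
toward the sideslip, a gentler counter-pulse, and recovery, spanning
about 15 wingbeats (0.58 s). During pulses the roll-contralateral wing
pair flies at higher pitch and sweep amplitude and lower elevation
amplitude, with the upstroke pitch asymmetry 50–80% of the downstroke
value — which is what produces the stair-step roll pattern (orientation
gained in downstroke, stalled or lost in upstroke). Asymmetry
magnitudes, the up/down ratio, bilateral amplitude boosts and
per-segment jitters are drawn independently per trial so the three
asymmetry channels are not collinear across the dataset; maneuvers
alternate direction. Maneuver pulses were chosen a few wingbeats long:
much shorter pulses concentrate the maneuver's spectral content where
the two-wingbeat differencing stencil attenuates it, which biases the
force-vector coefficients low — a filter property, not a physics one.

On these conditions the fitted $K_{\ddot y\beta}$ and $K_{\ddot
z\beta}$ land near one (the random-intercept-per-moth versions are
reported, mirroring the original best-by-AICc models), all velocity
coefficients are negative, the wing-pitch asymmetry drives roll
velocity positively, and the roll-velocity model decisively outfits
the roll-acceleration model. The measured $K_{\dot\beta\alpha}$ is
attenuated relative to the simulator's true torque gain — wing-pitch
asymmetry is the noisiest of the measured asymmetries, and
errors-in-variables bias shrinks its multivariate coefficient — so
tests assert its sign and the model ranking, not its magnitude.

## Reproducing the results

`scripts/acceptance.R` re-runs the entire study from a seed and writes
the fitted coefficients, model r² values, stroke-plane/body-roll
correlation, stair-step increments, hover trim amplitude, damping
half-lives and wand diagnostics as JSON. The testthat suite contains
the same checks at fixed seed plus the module-level oracles
(closed-form REML profile, exhaustive AICc enumeration, spherical
trigonometry for amplitudes, DLT round trips).

## Known limitations

* The quasi-steady decomposition omits wake capture, wing–wake
  interaction and wing flexibility; its constants are calibration
  choices, not measurements of any individual moth.
* Three body degrees of freedom: conclusions about yaw–roll
  interaction are out of reach by construction.
* Roll damping is faster than one wingbeat, so the roll damping
  half-life reported by the wingbeat-averaged probe is
  resolution-limited; treat it as an upper-bound scale, not a precise
  constant.
* The landmark noise model is isotropic and frame-independent, which
  is the most benign digitization error model; correlated digitizer
  bias would propagate differently.
* The free moth drifts slowly at large roll angles and velocities;
  commanded maneuvers keep the trajectories inside the
  quasi-linear envelope, as real maneuvers did.
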