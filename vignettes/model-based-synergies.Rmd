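---
title: "Model-based muscle synergies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based muscle synergies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic fixtures emulate
(and what they do not), the numerical choices, and the places where the
design was genuinely open. No empirical number is stated here that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

### Muscle mechanics

Each muscle is a rigid-tendon Hill model. Musculotendon length is a cubic
polynomial in the operational angle $\theta$ (rad), so the moment arm
$r(\theta) = -\,\mathrm{d}l/\mathrm{d}\theta$ is exactly consistent with the
length excursion — an invariant the tests check by finite differences.
Fibre length is musculotendon length minus tendon slack, normalized by the
optimal fibre length $l_{opt}$. Force is

$$F = a\, F_0^{max} f_l(\theta)\, f_v(\dot\theta)\, \cos\alpha,$$

with a Gaussian active force–length curve $f_l = \exp(-(l_n-1)^2/\gamma)$,
$\gamma = 0.45$ (dimensionless width; standard for fast curve families), and
a hyperbolic Hill force–velocity curve: $f_v = (1+v_n)/(1-v_n/k)$ for
shortening ($k = 0.25$ curvature), a Katz-type eccentric branch saturating
at 1.4. Velocities are normalized by $v_{max} = 10\,l_{opt}/s$. Passive
fibre force, activation dynamics and tendon compliance are deliberately
absent: the formulation is instantaneous, which is exactly what makes the
closed-form sharing argument available.

The activation-to-torque transform of muscle $i$ is
$h_i(\theta,\dot\theta) = F_0^{max} f_l f_v \cos\alpha\, r(\theta)$, the
torque produced per unit activation. Optionally $f_v$'s effective maximum
shortening velocity scales with activation ($0.25 + 0.75a$, a standard
scaling); because $h$ is then nearly flat in $a$ at physiological speeds, we
freeze the dependence at a reference $a_{ref} = 0.5$ and keep the switch
**off** by default. The flatness test bounds the relative change of $h$ over
$a \in [0,1]$ at $\dot\theta = 2$ rad/s by 0.6; the bound is generous
because our activation scaling is conservative at $a \to 0$, where the
muscle produces no force anyway (the transform's value there is moot).

### Optimal force sharing and synergies

Minimizing $J = \sum a_i^2$ subject to $\sum a_i h_i = T$, $a_i \ge 0$ gives
the KKT solution: agonists ($\operatorname{sign} h_i = \operatorname{sign}
T$) take $a_i = h_i T / \sum_{j \in agonists} h_j^2$, antagonists are zero.
The denominator runs over the *agonist set only* — with antagonists clamped
at zero this is what makes the equality constraint hold exactly; summing
over all muscles would not. The ratio $a_i/a_{rep} = h_i/h_{rep}$ between
active muscles is torque-independent, which is the definition of the
posture-dependent synergy ratio

$$S_i^{+} = \max(0,\, h_i/h_{rep+}), \qquad
  S_i^{-} = \max(0,\, h_i/h_{rep-}),$$

stored on a grid over $\theta$. A *representative* muscle must keep a strict
torque sign over the whole workspace; `validate_representatives()` enforces
this and reports, per muscle, whether it is always-positive, always-negative
or function-switching. Reconstruction is
$a_i = a_+ S_i^{+}(\theta) + a_- S_i^{-}(\theta)$ with linear interpolation.

No upper activation bound is imposed: for sub-maximal demands the quadratic
cost keeps activations below 1 on its own, and a warning flags demands that
leave that regime.

### Controllers

The synergy-PID emits a **signed activation**
$u = \mathrm{clamp}(K_p e + K_i \int e + K_d \dot e, -1, 1)$ on the angle
error; $\max(u,0)$ drives the positive synergy and $\max(-u,0)$ the negative
one. The derivative acts on a 50 Hz first-order-filtered error; the integral
freezes while the output saturates (clamping anti-windup).

The FSO baseline minimizes, every step,
$w_1 \sum a_i^2 + w_2(\theta^+ - \theta_{des})^2 +
 w_3(\dot\theta^+ - \dot\theta_{des})^2$ over $a \ge 0$, where
$(\theta^+, \dot\theta^+)$ is a one-step prediction. Two deliberate choices:

- the error terms are **squared** — a linear penalty would be unbounded
  below and cannot define a minimum;
- the prediction is **semi-implicit** Euler
  ($\dot\theta^+ = \dot\theta + \Delta t\,\ddot\theta(a)$,
  $\theta^+ = \theta + \Delta t\,\dot\theta^+$) rather than plain forward
  Euler, because under plain forward Euler $\theta^+$ does not depend on the
  activations at all and the $w_2$ term would be inert.

Since muscle torque is exactly linear in $a$ (activation dependence of $f_v$
off), each FSO step is a nonnegatively-constrained convex QP, solved exactly
by the same dense active-set routine that backs `qp_oracle()`. Both
controllers run at the integrator rate (1 kHz).

Default weights/gains are the planar-task values
($w = (1, 3\times10^6, 5\times10^2)$; $K = (10, 10, 2)$). The steering-task
column of the conventional parameter set ($K_p = K_i = 100, K_d = 0$)
belongs to a specific 3-D multibody plant; on our surrogate crank fixture
(effective inertia 0.1 kg m², viscous damping 0.1 N m s/rad) it produces a
nearly undamped ~35 Hz limit cycle with saturated activations, so crank
experiments use the planar defaults. This is a property of the fixture, not
of the method.

## 2. The synthetic world

No external data exist in this problem: both plants are *stated worlds*.

**Forearm fixture.** Seven elbow muscles (brachioradialis, brachialis, two
biceps heads, three triceps heads) with strengths, fibre lengths and
pennation angles in the range of standard published upper-limb models, and
smooth quadratic moment-arm profiles peaking near mid-flexion (flexors
+1.8–5.5 cm, extensors −1.7 to −2.4 cm). Joint range $[0, 2.6]$ rad,
effective inertia 0.072 kg m² (forearm-plus-hand about the elbow), damping
0.05 N m s/rad, gravity zero (horizontal-plane convention). These values are
documented stand-ins chosen once for physiological plausibility: the
original planar model's parameters live in cited references, so ratio
surfaces can only be matched qualitatively.

**Crank fixture.** `make_crank_model(seed)` generates a planar crank whose
muscles are random cubics constrained so that muscle 1 is always a
counter-clockwise rotator, muscle 2 always clockwise, and muscle 3 *changes
function* (its $h$ crosses zero) somewhere in $[-\pi/2, \pi/2]$ — the
qualitative signature of multi-joint steering models, where most muscles
switch rotation direction with wheel angle and therefore cannot serve as
representatives. Generation retries within bounds and is bitwise
deterministic in the seed.

**Trajectories.** Seeded sum-of-three-sines, frequencies drawn from
0.1–0.5 Hz, total amplitude 60% of the half-range, centred mid-range — slow,
sub-maximal, reaching-scale motion. The random-motion distribution behind
the conventional NNMF training protocol is unspecified in the literature we
model; this is a documented stand-in.

**What a green test does not establish.** The fixtures contain no
co-contraction demands, no noise, no activation dynamics, and the
controllers know the plant exactly. Effort levels are therefore much smaller
than published whole-task numbers, and all comparisons are *within-world*
(controller vs controller on the identical task), never reproductions of
published magnitudes.

## 3. NNMF baseline

Training data are closed-form optimal activations sampled along a seeded
random motion (inverse dynamics gives the demanded torque; the optimum
shares it). Factorization is Lee–Seung multiplicative updates on the
Frobenius objective, $n = 2$, 10 seeded restarts, at most 5000 iterations,
stopping when the per-iteration objective decrease falls below $10^{-8}$
times the *current* objective — relative-to-current so that exactly
factorizable matrices converge to machine accuracy instead of stalling at a
plateau threshold tied to the initial scale. Synergy columns are assigned to
torque directions by representative dominance (tie-break: torque sign of
$\sum_i S_i h_i$ at mid-range) and rescaled so the representative's weight
is exactly 1; the product $SC$ is unchanged.

Because multiplicative updates approach exact zeros only asymptotically,
envelope tests comparing static weights against posture-dependent ratio
ranges carry a $10^{-3}$ numerical slack.

## 4. Numerical choices

- **Integration**: classical RK4, fixed $\Delta t = 1$ ms; hard joint stops
  clip the angle and zero the velocity; intermediate RK4 stages that poke
  past a stop are evaluated at the stop. Halving $\Delta t$ moves a 1 s
  trajectory by $< 10^{-6}$ rad (tested).
- **QP**: a primal active-set method on the KKT system (dense `solve()`),
  handling nonnegativity plus an optional single equality. Tolerance
  $10^{-9}$. It is the package's independent check on the closed form — no
  QP library in the supported environment provides this, so it is
  implemented here and itself property-tested against KKT conditions on
  random problems.
- **Synergy grid**: 101 uniform $\theta$ points, linear interpolation;
  velocity-dependent tables (off by default — $h$ is weakly
  velocity-dependent at physiological speeds) use bilinear interpolation.
  $h$ is evaluated at $a_{probe} = 0.5$, $\dot\theta = 0$.
- **Degenerate inputs**: zero demanded torque returns exact zeros; a
  representative with $h = 0$ anywhere on the grid raises an
  `invalid_representative` error naming the posture; all-zero activation
  matrices are rejected by the factorizer.

## 5. Known limitations and one red acceptance check

- One-dimensional operational spaces only; higher-dimensional spaces need
  $n+1$ synergies and a positive-decomposition construction that is out of
  scope here.
- No EMG handling: the "data" the NNMF baseline consumes are simulated
  optima, mirroring the model-based protocol.
- Computation-time claims are not measured (hardware-dependent).
- **Controller error ratio.** The acceptance suite requires the synergy-PID
  to track within twice the FSO baseline's RMS error. In this package's
  stated world that check fails and is left failing, deliberately: the FSO
  holds an *exact* model of a smooth deterministic plant, so its only error
  source is the mismatch between its one-step prediction and the RK4
  integrator — it tracks at integration precision (microradians). A
  finite-gain PID without feedforward has an error floor set by the inertial
  demand over the loop gain (a tenth of a milliradian here, excellent in
  absolute terms), so the *ratio* is orders of magnitude above 2 and, because
  both errors scale linearly with demand, no trajectory amplitude changes
  it. Both controllers are "very close" in every absolute sense — effort
  within a few percent, activation patterns cosine-similar above 0.9,
  sub-milliradian tracking — and the effort and similarity checks pass. The
  ratio criterion implicitly assumes an FSO with a non-negligible error
  floor (e.g., an inexact inner solver or plant mismatch); degrading our FSO
  to manufacture such a floor would make the baseline worse to make a test
  green, which we decline to do.

## 6. Reproducing the numbers

```{r}
# full property-based acceptance report (a few minutes, one CPU):
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
# unit + acceptance tests:
#   testthat::test_dir("tests/testthat", package = "motorsynergy",
#                      load_package = "installed")
```

Every quantity in the report is recomputed from scratch at run time from the
given seed; nothing is looked up.
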