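---
title: "Goal Babbling, motor synergies, and how this package models them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal Babbling, motor synergies, and how this package models them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalbabbling)
```

## The scientific problem

A reaching goal in the plane has two coordinates; a three-joint arm has
three. The inverse mapping from goals to postures is therefore
underdetermined: every reachable point corresponds to a one-dimensional
family of postures, and points near the origin of the workspace can be
reached by a vast set of joint configurations. How a learner resolves this
redundancy — which postures it ends up using, and how many degrees of
freedom those postures effectively span — is the central question this
package makes computationally reproducible.

The task is a planar kinematic chain with segment lengths
$l_1 = 0.55$, $l_2 = 0.225$, $l_3 = 0.225$ (total reach 1, arbitrary
units), no joint limits, and forward kinematics

$$x = \sum_{k=1}^{3} l_k \cos\Big(\sum_{j\le k} q_j\Big), \qquad
  y = \sum_{k=1}^{3} l_k \sin\Big(\sum_{j\le k} q_j\Big).$$

Two *home postures* seed learning: $H_1 = (\tfrac34\pi,\, 1.99,\, \pi)$
and $H_2 = (1.51,\, 1.99,\, 0)$. Both reach the same goal point
$(-0.39, 0.39)$, but they sit in different regions of motor space, and —
crucially — they differ in which joints are locally effective: at $H_1$
the two distal segments fold back onto each other, so joint 2 moves the
endpoint only at second order, while at $H_2$ the distal segments are
extended and joint 2 is the second-most effective degree of freedom.
Training uses 16 targets on a regular polar grid (radii 0.25–0.85, angles
$\tfrac14\pi$–$\tfrac34\pi$); nine further targets (five interior, four
exterior) are used only for evaluation.

One geometric note: the source description places two interior test
targets at polar angle $\tfrac43\pi$, outside the trained quarter segment,
while describing all five as interior. We read this as a typo for
$\tfrac13\pi$ and default to that corrected layout
(`build_task_geometry("corrected")`); the verbatim variant remains
available as `"printed"` for audits. Nothing in the package asserts which
was intended.

## The Goal Babbling learner

Goal Babbling learns the inverse model $g: (x, y) \mapsto q$ *directly*,
without first learning a forward model. The package's learner
(`goal_babbling()`, with the machinery exposed via `init_learner()`,
`training_step()` and friends) is a mixture of local affine models: 16
prototypes centred on the training targets, Gaussian responsibilities in
goal space (bandwidth = the median nearest-neighbour target spacing,
0.2), prediction by the responsibility-weighted sum of the local maps.
At initialization all gains are zero and all offsets equal the home
posture, so the untrained model maps *every* goal onto the home posture —
the minimal policy from which exploration must expand.

Each of the 1000 online updates per block (40 targets, reached via 25
linear sub-goal interpolation steps each) does the following:

1. **Execute with exploration.** The command is
   $q^+ = \hat q(x^*) + e(x^*, t)$. The noise is affine in the goal,
   $e = A_t\,(x, y, 1)^\top$, each coefficient of $A_t$ performing a
   Gaussian random walk with per-step standard deviation
   $\sigma_\Delta = 0.005$, and the rows of $A_t$ renormalized after
   every step so the induced perturbation has standard deviation
   $\sigma = 0.5$ rad per joint over the unit goal box — equal amplitude
   for all joints by construction. The slow walk keeps behaviour
   continuous while gradually sweeping new directions of motor space.
2. **Minimize effort.** The executed posture is relaxed towards home
   within the null space of the task Jacobian:
   $q^+ \leftarrow q^+ + \alpha\,(I - J^+ J)(q_{\text{home}} - q^+)$
   with $\alpha = 1$ by default, i.e. every executed posture is the
   first-order effort-optimum for its own endpoint. This is the
   package's reading of the effort-minimizing cost the agents are
   described as following. It matters: without it, goal-irrelevant
   perturbations of locally *ineffective* joints are slowly absorbed
   into the learned map (nothing ever corrects them, precisely because
   they do not move the endpoint), and the learned solutions lose the
   condition-specific structure described below. With it, the null-space
   component is continuously stripped from the training data.
3. **Observe and regress.** The actual endpoint
   $x_{\text{obs}} = f(q^+)$ is observed, and one gradient step with
   rate $\eta = 0.2$ pulls the model's prediction *at the observed
   endpoint* towards the executed posture. Regressing on
   $(x_{\text{obs}}, q^+)$ rather than $(x^*, q^+)$ is the defining Goal
   Babbling trick: the sample is always kinematically valid, so the
   inverse model can be learned directly from scratch. Updates are
   weighted by a direction term
   $\max(0, \cos(x_{\text{obs}} - x_{\text{prev}},\; x^* - x_{\text{prev}}))$
   — movement in the intended direction is reinforced — and an
   efficiency term $\min(1, \lVert\Delta x\rVert / \lVert\Delta q\rVert)$
   that discounts large motor excursions with little goal effect. Both
   follow the local-linear-map literature this learner descends from and
   can be disabled in `gb_config()`.

Blocks have no meaning to the algorithm; they exist so that after each
block the model can be read out on the nine test targets with noise and
learning disabled (`evaluate_test()`). Populations
(`run_population()`) train 100 agents per condition, agent $i$ seeded
with `base_seed + i`.

Because test-phase postures are predictions of a smooth map from a 2-D
goal space, they lie on a two-dimensional sheet in motor space; PCA of
the nine final-block test postures therefore concentrates variance in
two components (the acceptance threshold of 90% is met with a wide
margin, typically >99%). The scientifically interesting structure is
*which* sheet each condition settles on: solutions stay near their own
home posture, and the loading of joint 2 on the first synergy is small
for $H_1$ populations but large for $H_2$ populations — the learner
incorporates the degrees of freedom that were effective where it
explored.

## The human-facing task transformations

Human participants experience the same task through deliberately
unfamiliar codes, all implemented in the package because the synthetic
generator and the morphology analysis need them: three finger
elevations drive the three joints through a random signed permutation
(48 possibilities; 5 cm of elevation = $\pi$ rad; level fingers =
baseline posture $q^* = (1.93, 1.99, \tfrac{\pi}{2})$, the midpoint of
$H_1$ and $H_2$); goals are displayed as ellipses (x linearly sets the
base radius in $[0.66°, 3.30°]$, y the elongation in $[-0.5, 0.5]$);
feedback is the score $\big(\max(0, 1-d)\big)^2 \cdot 100$. The printed
form of that score, $\max(0,(1-d)^2)\cdot 100$, has a vacuous clamp and
would *rise* again for $d > 1$; we clamp before squaring for
monotonicity and keep the literal form behind `printed_literal = TRUE`.
Similarly, the printed ellipse radii "$1 \pm e$" omit the base radius;
we scale them by $r$ so that size and shape compose. Training blocks
are an 80-second tour of the 16 training targets in random order, 5 s
per linear segment. Counterbalancing pairs each participant starting in
$H_1$ with one starting in $H_2$ who reuses the same mapping sequence,
so every mapping occurs once per condition.

## The synthetic session generator

`generate_session()` does **not** simulate trial-by-trial human
learning. It is a parametric model of the *statistical signatures* the
analysis pipeline is designed to detect, with every signature planted
explicitly so it can be recovered:

* a **solution plane**: an orthonormal 3×2 basis through the block's
  central posture $c_b = H + \lambda_b (q^* - H)$; intended postures are
  inverse-kinematics solutions constrained to that plane (damped
  Gauss–Newton in the two plane coordinates, multistart, keeping the
  branch closest to the centre so the expert sheet is compact);
* a **home bias** $\lambda_b$ (default 0.3 throughout), placing the
  solutions between the condition's home posture and the baseline;
* **motor noise**: in-plane Gaussian noise with per-block standard
  deviation decaying 0.6 → 0.2 rad and out-of-plane noise decaying
  0.3 → 0.05 rad, so early sessions are variable and weakly planar and
  late sessions are consolidated;
* **missing trials**: each test trial independently lost with
  probability 0.014, whole-trial (the motion sensor loses all three
  fingers at once), carrying no posture downstream.

The default plane is condition-adapted: it is spanned by the $q_1$ axis
(whole-arm rotation, which controls reach angle) and a radius synergy
$(0, \cos\varphi, \sin\varphi)$ with $\varphi = 60°$ for $H_1$
(q3-dominant) and $\varphi = 30°$ for $H_2$ (q2-dominant). These are the
orientations from which a single plane reaches all 25 targets with a
compact solution sheet — and they mirror the condition-dependent
degree-of-freedom use the agent simulations produce. The schedules are
configuration values chosen to give the analysis qualitatively
human-like input, not estimates of any participant's parameters; what
passing recovery tests show is that the *pipeline* detects planted
structure of this kind and strength, not that real participants conform
to the generator.

## The analysis pipeline

Angles are analysed *unfolded*: values outside $[0, 2\pi)$ are kept,
because finger movements are not circular even though their goal-space
effect is. Test reaches are pooled into windows — three consecutive
blocks (27 postures) for 24-block human-like sessions, one block (9
postures) for 10-block agents, since three points per window per target
are unnecessary in a 3-D motor space — and each window gets a
covariance PCA with no scaling (`pca_synergies()`). Loadings follow a
fixed sign convention (largest-magnitude entry positive) so loading
comparisons are deterministic despite the PCA sign ambiguity. Windows
with fewer than 4 rows or zero variance are excluded and counted, never
imputed.

Derived measures: variance fractions per synergy; the central posture's
projection $s$ on the $H_1$–$H_2$ line ($s(H_1)=0$, $s(H_2)=1$,
$s(q^*)=0.5$ up to the 3-digit rounding of the printed $q^*$); the
absolute $q_2$ entry of PC1; the summed variance (trace of the posture
covariance); per-block mean reach error with the no-movement baseline
as companion; and the morphology contrast — PCAs of pooled reaches in
task space versus finger-elevation space, which dissociate because
mappings are randomized across participants.

## Statistics

The repeated-measures machinery is implemented from first principles
and checked against brute-force oracles in the test suite: a two-way
fully-within rmANOVA (classical SS decomposition, each effect tested
against its unit-interaction term, partial $\eta_p^2 =
SS_{\text{eff}} / (SS_{\text{eff}} + SS_{\text{err}})$), an exact sign
test, a Wilcoxon signed-rank test (exact by enumeration up to $n = 12$,
tie-corrected normal approximation with 0.5 continuity correction
beyond), and a tie-corrected Friedman test. The grouping unit for the
ANOVA is the finger mapping, not the participant: with the
counterbalanced roster each mapping has exactly one session per
condition, which is what makes Condition a within-unit factor. Units
with incomplete cells are dropped listwise. Sphericity corrections are
off by default (a Greenhouse–Geisser option exists) since the design
this mirrors reported uncorrected degrees of freedom. All four tests
hold their nominal size within [0.03, 0.07] at $\alpha = 0.05$ under a
seeded Gaussian null in the test suite.

## Numerical choices and edge cases

* Exploratory-noise normalization uses the second-moment metric of the
  unit goal box ($E[x^2] = E[y^2] = \tfrac13$), so "amplitude $\sigma$"
  is an average over the goal region; at a fixed goal the amplitude
  varies smoothly with eccentricity. Amplitude and continuity are
  validated by Monte-Carlo tests, run at a faster walk step than the
  study value because a walk with relative step $\sigma_\Delta/\sigma =
  0.01$ decorrelates over $\sim 10^4$ steps and a sample standard
  deviation over $10^5$ steps would estimate almost nothing.
* With $\sigma = 0$ the perturbation is exactly zero and the effort
  projection is skipped (the executed posture equals the prediction);
  with $\eta = 0$ the model is frozen. Both limits are asserted.
* Inverse kinematics is damped least squares; the plane-constrained
  variant used for planting runs multistart Gauss–Newton on a small
  polar grid of plane coordinates and prefers the converged branch of
  minimal norm. Non-convergence within 0.01 flags the target.
* The session schema stores numbers at 17 significant digits; round
  trips are bit-exact and missing trials are explicit nulls.
* Agent populations of 100 and the synthetic roster of 20 participants
  are the study sizes and the defaults everywhere; module-level tests
  use smaller populations (3–20 sessions) where only structure, not
  population statistics, is under test.

## Known limitations

The learner is a faithful member of the local-linear-map Goal Babbling
family rather than a bitwise reimplementation of any specific prior
codebase; population-level behaviour, not parameter-level identity, is
the validated contract. The synthetic generator makes no claim to fit
the deposited human dataset — its training-phase kinematics are
schematic, and its schedules are design values. The importer for the
deposited archive is contract-complete (field-map driven, count and
missing-trial validation) but can only be exercised against synthetic
stand-ins here; the handful of published human statistics that require
the real archive (rmANOVA F values, the 175 discarded trials) are
therefore reproducible only after downloading it.
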