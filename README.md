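# goalbabbling

Simulation and analysis of redundancy resolution in motor skill
acquisition: how a learner that receives only goal-related feedback comes
to use a small set of motor synergies when a task admits infinitely many
solutions.

The package is written for computational motor-control researchers. It
provides three things:

1. **A Goal Babbling agent** for a redundant three-joint planar reaching
   task. The arm has segments (0.55, 0.225, 0.225) and forward
   kinematics
   `x = Σ l_k cos(q_1 + … + q_k)`, `y = Σ l_k sin(q_1 + … + q_k)`.
   The agent learns the inverse model `g : (x, y) → (q1, q2, q3)`
   directly and online: it executes its current estimate plus
   exploratory noise `e(x*, t)` (a slow, bounded random walk of
   goal-linear perturbations, amplitude σ = 0.5, step σΔ = 0.005),
   relaxes the executed posture towards its home posture within the
   Jacobian null space (effort minimization), observes the endpoint,
   and regresses the model at the *observed* endpoint towards the
   *executed* posture with learning rate η = 0.2. Training runs 10
   blocks of 1000 updates (40 targets × 25 interpolation steps) from
   one of two home postures, H1 = (¾π, 1.99, π) or H2 = (1.51, 1.99, 0),
   which reach the same point (−0.39, 0.39) but make different joints
   effective.
2. **A synthetic session generator** producing human-like 24-block
   sessions (counterbalanced 20-participant design, signed
   finger-to-joint mappings, ellipse goal code, scores, ~1.4% missing
   trials) with planted ground truth — a 2-D synergy plane, a home-bias
   coefficient, decaying noise schedules — so the whole analysis
   pipeline is testable by parameter recovery without any data download.
3. **The synergy analysis pipeline and statistics**: windowed
   covariance PCA of unfolded joint angles (27 postures per 3-block
   window for humans, 9 per block for agents), variance-explained
   trajectories, solution location on the H1–H2 line, |q2| loadings,
   summed variance, reach-error curves, morphology-vs-task PCA, and
   from-scratch repeated-measures statistics (two-way rmANOVA with
   partial η², exact sign test, Wilcoxon signed-rank, Friedman) that
   are verified against enumeration oracles.

## Worked example

Train one agent from the H2 home posture and inspect it:

```r
library(goalbabbling)
fit <- goal_babbling("H2", seed = 1)
print(fit)
#> Goal Babbling agent (condition H2, 10 blocks, seed 1)
#>   mean test error: block 1 = 0.505, final = 0.17 (baseline 0.493)
summary(fit)
#> Goal Babbling agent, condition H2
#>   updates: 10000
#>   mean test error per block:
#>     0.505 0.501 0.489 0.467 0.421 0.379 0.315 0.228 0.178 0.17
#>   baseline (no movement): 0.493
#>   final-block synergies, variance fractions: 0.847 0.151 0.002
```

The per-block error is the mean distance between the nine test-target
goals and the endpoints the frozen model reaches (learning and noise
disabled during tests). It starts at the no-movement baseline — the
untrained model maps every goal onto the home posture — and falls as
goal babbling expands the repertoire. The final variance fractions say
that two principal components (motor synergies) carry 99.8% of the
posture variance across test reaches: the agent has collapsed the
redundant 3-D motor space onto a 2-D solution sheet.

Population-level structure, e.g. the condition-dependent use of joint 2:

```r
pop1 <- run_population("H1", n_agents = 20, base_seed = 500)
pop2 <- run_population("H2", n_agents = 20, base_seed = 500)
q2_of <- function(s) q2_loading(pca_synergies(
  as.matrix(s$blocks[[10]]$test[, c("q1", "q2", "q3")])))
median(sapply(pop1$sessions, q2_of))  # 0.278  (H1: q2 barely used)
median(sapply(pop2$sessions, q2_of))  # 0.816  (H2: q2 in the first synergy)
```

Synthetic human sessions and the analysis pipeline:

```r
pop <- generate_population(20, seed = 1)          # 40 counterbalanced sessions
an  <- analyze_sessions(pop$sessions, bin_size = 3)
head(an$location)   # central-posture coordinate on the H1-H2 line, per window
head(an$fractions)  # variance fraction per synergy, window, session
```

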