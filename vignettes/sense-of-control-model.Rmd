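---
title: "A situational sense of control for task-switching agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A situational sense of control for task-switching agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soctask)
```

## The problem

Serial multitasking — two tasks running concurrently while only one can be
perceived and controlled at a time — forces a controller to decide *when to
switch*. This package models a cognitive quantity hypothesized to drive
that decision: a **situational sense of control (SoC)**, a per-timestep
signal in $[0,1]$ composed of two ingredients,

* a **prediction error** (PE): how surprising the last action outcome was,
  relative to an internal forward model, and
* a **need for control** (NfC): how much worse the near future would be if
  the task were left to run unattended.

The SoC at time $t$ is

$$\mathrm{SoC}_t = 1 - \frac{\mathrm{PE}_t + \mathrm{NfC}_t}{2},$$

so full control (1) requires both an unsurprising world and no pending
demand for intervention. A hierarchical reinforcement-learning (RL) agent
uses this signal — as observation, as reward, or both — to learn a
task-switching policy over two "Collect Asteroids" subtasks.

## The subtask simulator

Each subtask is a vertical corridor of 9 playable columns flanked by
walls. The ship descends one row per step for 470 steps; actions are
left / no-steer / right. The difficulty sets the asteroid count: 14
(easy) or 30 (hard). An asteroid is collected when the ship occupies its
cell at the step its row is reached, and missed otherwise; every asteroid
is resolved one way or the other, so the success rate
$SR = \#\text{collected} / \#\text{asteroids}$ is always defined.

**Input noise.** When enabled, every executed left/right move is perturbed
by a draw from $\mathcal N(0, 1.5)$, added to the unit displacement and
rounded to the nearest integer (the state space is discrete), then clipped
at the walls. The no-steer action is never perturbed — noise attaches to
*moves*, not to drift. This is the only stochastic element of the dynamics
and the sole source of irreducible (aleatoric) prediction error.

**Geometry defaults.** The corridor width (9), visibility window (10 rows
of lookahead) and one-asteroid-per-row placement are package choices;
the sources define counts and episode length but not the pixel-to-cell
mapping. All three are configurable in `env_config()`.

**Asteroid-free phases.** Two 40-step spans — at the episode start and
centred on the midpoint — are kept free of asteroids, giving phases in
which no control is needed. Placement additionally keeps
`placement_margin = window + horizon - 1 = 19` rows after each span
clear. The margin matters: the NfC rollout launched from the last
decision of a span reaches `horizon - 1` steps ahead, and each imagined
state sees `window` rows further. With the margin, *no* state of *any*
rollout launched inside a span can perceive an asteroid, so NfC is
exactly zero throughout the span rather than merely small.

## Rewards

Two reward modes exist.

**Dense (shaping) reward** — used by the learning agents. The positional
state is treated as an occupancy image of the visibility window; a
Gaussian blur ($\sigma = 1$ cell) spreads each pending asteroid's
intensity, and the reward reads the blurred value at the ship's cell. A
distance term decreasing linearly in the horizontal offset to the nearest
incoming asteroid promotes early alignment. Both components are
normalized to $[0,1]$, weighted equally and scaled to a peak of 100.

Two design points deserve emphasis:

* *Intensity.* The NfC definition divides a discounted rollout-return gap
  by 100 before clamping to $[0,1]$. With unit-scale rewards that gap
  could never come close to 100 and NfC would be pinned near zero; the
  peak of 100 makes the gap commensurate with its normalizer, so NfC
  actually spans its range (`reward_scale` in `env_config()`).
* *Transition timing.* The reward of a step is evaluated at the post-move
  ship position **before** the current row's asteroid is resolved. If one
  evaluates after resolution, the reached asteroid vanishes from the
  reward field whether it was collected or missed — missing becomes
  cost-free, and a reward-maximizing learner is taught to abandon its
  current target early in favour of the next one. Evaluating on the
  moved-but-unresolved state makes arriving aligned itself maximally
  rewarding.

**Sparse reward** — the human-facing scoring: $+m$ per collection, $-m$
per miss, $m = 100/N$, so a perfect episode totals $+100$ and a fully
missed one $-100$.

## Forward model, PE and NfC

The forward model is the deterministic one-step map of the noiseless
dynamics: ship column moves by the commanded unit displacement (clipped),
every entity advances one row, collection events resolve by the
environment's own rule. It is deliberately unaware of input noise, so
with noise off its predictions are exact (and PE $\equiv 0$), while with
noise on the discrepancy is precisely the rounded noise displacement.

PE normalizes the column discrepancy through a hyperbolic tangent,
$\mathrm{PE} = \tanh(0.5\,|x - \hat x|)$: a miss of 4 columns already
saturates near 1. Min–max scaling was rejected because realized
discrepancies concentrate on $\{0, 1, 2\}$ columns while the theoretical
maximum is the corridor width — the tanh keeps the common range
informative. Only the ship's column enters: noise affects nothing else.

NfC compares two imagined futures from the current state, both computed
by iterating the forward model for `horizon = 10` steps: one steered by
an *optimal* policy, one receiving only the default (no-steer) action.
Rewards along each trajectory are summed with weights $\gamma^k$
($\gamma = 0.9$, first element unweighted), and

$$\mathrm{NfC}_t = \min\!\big(\max(rs^o_t - rs^d_t, 0) / 100,\ 1\big).$$

The horizon of 10 (unstated in the sources) spans the approach time of
the nearest visible asteroid at the default geometry; rollouts truncate
at the episode end. The "optimal" policy defaults to a deterministic
greedy oracle — steer toward the nearest visible pending asteroid, ties
toward the centre — which makes NfC well-defined and testable without any
training; a trained sub-agent policy can be plugged in instead
(`nfc_policies`). The gap is floored at zero before scaling: an idealized
optimal policy never trails the default one, but a merely-trained
stand-in can.

## The hierarchy

Two environments advance in lockstep. Every `decision_interval = 5`
frames the meta-agent chooses the active task; the chosen sub-policy
emits five actions into its environment while the other environment
receives five default actions. A 470-step episode therefore has exactly
94 decision points. Decisions sit on a fixed 5-frame grid (not merely a
minimum gap): the always-switching baseline's exact count of 94 switches
per episode implies a grid.

**Switch counting.** A decision counts as a switch when its chosen task
differs from the previously active one. For the first decision the
reference is a configurable pre-episode task (default task two), and the
switch-every-frame baseline toggles starting from task one — so it
realizes a switch at all 94 decisions while its choice sequence starts
`0, 1, 0, …`.

**Observations.** In `world_state` mode the meta-agent sees the true
positional encoding of the active task concatenated with a
forward-model-propagated belief about the inactive one, plus an explicit
active-task indicator (without the indicator the POMDP is needlessly
aliased). Because the default action is never noise-perturbed, the
belief of an unattended task is exact even in noisy tasks. In `soc` mode
the observation is just the measured SoC of the active task and the
decayed estimate of the inactive one, plus the indicator.

**Inactive-task decay.** The unattended task's SoC estimate decays by
$\phi = 0.1$, floored at zero, **once per meta decision**. We considered
applying the decay per frame, but five frames per decision would drive
any estimate to zero within two decisions; the optimal response to the
SoC-difference reward then degenerates into switching at every decision
point, indistinguishable from the switch-every-frame baseline — contrary
to the moderate switch counts the SoC mechanism is meant to produce.
Per-decision decay retains a graded estimate over the several-decision
timescale on which switching decisions actually play out. On switching
back, the task's SoC is remeasured from fresh PE and NfC at the next
decision boundary.

**Meta rewards.** The `active` reward sums the attended environment's
rewards over the five frames. The `soc` reward is $+1$ for choosing the
task with the strictly lower SoC (the one sensed as needing attention),
$-1$ for the higher, $0$ on ties. Crossing the two observation modes with
the two reward modes yields the four meta-agent variants (`no_soc`,
`soc_as_observation`, `soc_as_reward`, `soc`).

## Training

All agents train with an in-package implementation of Proximal Policy
Optimization: a shared tanh hidden layer, softmax policy and linear value
heads, generalized advantage estimation, the clipped surrogate objective
and Adam. Gradients are exact (they are verified against finite
differences in the test suite), and every source of randomness flows
through R's RNG, so training is reproducible under a seed.

Positional observations use fixed-length arrival-ordered slots: the five
soonest visible asteroids as (rows-to-go, horizontal offset) pairs with
zero sentinels, plus the ship column and episode-time fraction. Ordering
by arrival puts the current target in a fixed slot, which a small network
exploits far more readily than a per-row occupancy layout.

Default hyperparameters (all exposed via `ppo_hp()`):

| target | hidden | lr | $\gamma$ | batch | notes |
|---|---|---|---|---|---|
| sub-agent | 64 | 2e-3 | 0.9 | 1880 | rewards scaled by 0.01 for conditioning |
| meta, SoC reward | 16 | 1e-2 | 0.3 | 188 | reward is immediate; short credit horizon |
| meta, active reward | 32 | 1e-3 | 0.95 | 376 | rewards scaled by 0.002 |

The SoC-difference reward depends only on the current observation and
choice — a contextual-bandit structure — which is why a low discount and
aggressive step size converge within a 10,000-decision budget.

Step budgets come in two presets. `paper` holds the study-scale budgets
(sub-agents $10^7$ environment steps; meta-agent $1.3\times 10^6$
decisions with the active reward, $10^4$ with the SoC reward, whose
learning curve converges early). `desk` is sized for a single CPU: sub
200,000 steps, meta active 100,000, meta SoC 10,000. Desk-scale absolute
success rates undershoot full-budget ones (most severely for the
active-reward meta-agent, whose budget shrinks 130-fold); ordering
comparisons between agents trained at matched budgets remain meaningful,
and that is what the package's acceptance checks assert. The
hyperparameter search is a fixed-seed random search over learning rate,
discount, GAE $\lambda$ and entropy coefficient — the four dimensions the
study names — selecting the trial with the highest mean training reward.

## Evaluation

`enumerate_blocks()` lists the ten difficulty-by-noise configurations
(noise on exactly one task of an equal-difficulty pair attaches to task
one, by the naming convention of the block ids). `evaluate()` runs every
agent over the *same* per-episode world seeds, so cross-agent contrasts
are not driven by world sampling, and aggregates: overall and per-task
success rates, engagement ratio of task one, switch counts, per-decision
switching ratios (with asteroid-free phases flagged), and the number of
visible asteroids at switch versus non-switch decisions — the attended
task's count at the moment the decision is taken. Block-level inference
(`block_statistics()`) is a one-way ANOVA across agents, Bartlett's
homoscedasticity test, and all pairwise two-tailed Welch t-tests with
Holm-adjusted p-values at $\alpha = 0.05$; the Holm step-down rule is
implemented directly and cross-checked against `stats::p.adjust` in the
tests.

## What the generator does and does not emulate

The world generator reproduces the study conditions: the asteroid counts,
the 470-step episodes, the rounded-Gaussian input noise, the asteroid-free
phases, and uniform placement over playable columns and eligible rows.
It does not emulate human-facing aspects — frame pacing, monitors, key
bindings — nor multi-asteroid rows (excluded by default to keep the
collect-or-miss bookkeeping per step unambiguous). Consequently, passing
tests demonstrate the mechanism — that a SoC-driven switcher can exploit
predictability and control demand — on this simulator; they do not by
themselves establish effect sizes for human behaviour or other task
domains.

## Numerical and degenerate-input choices

* Decay residues below $10^{-12}$ snap to zero, so the estimate reaches
  its floor in exactly $\lceil \mathrm{SoC}/\phi \rceil$ applications
  despite floating-point subtraction.
* Greedy-policy ties (two visible asteroids equally near) break toward
  the smaller horizontal offset, then toward the corridor centre.
* `success_rate()` refuses mid-episode states; `env_step()` refuses
  stepping past the episode end; asteroid placement that cannot satisfy
  the spacing constraints is a configuration error at `env_config()`
  time.
* An all-degenerate set of success-rate samples (zero variance in every
  group) skips the inferential tests and reports the degeneracy instead.

## Known limitations

The SoC model is predictive only — it carries no "postdictive" agency
cues such as outcome feedback — and no SoC is defined for the meta-agent
itself. The forward model is the exact noiseless dynamics rather than a
learned predictor, so all prediction error is aleatoric by construction.
Desk-scale training budgets under-train the active-reward meta-agent
relative to the study scale, which should be kept in mind when reading
absolute (rather than paired) success rates.
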