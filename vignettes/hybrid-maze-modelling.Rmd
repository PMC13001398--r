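---
title: "Modelling gridworld maze behaviour as a model-based/model-free mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gridworld maze behaviour as a model-based/model-free mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazerl)
```

## The behavioural setting

`mazerl` models discretized trajectories through small gridworld mazes:
an actor (a human participant in the motivating experiments, or a
simulated agent) repeatedly moves from varying start cells to a fixed
target cell on a 10 × 10 grid, around blocked cells, over 25 mazes with
10 trials each. The data unit is the *step record*: one executed
transition between 4-adjacent cells, together with any block contacts
that preceded it within the same step window. Three sensory conditions
change what the actor can know about the layout: `visual_haptic` (the
map is fully visible), `haptic` (the layout must be learned by touching
blocks), and `navigation` (a 3 × 3 window around the current cell is
visible, as in first-person navigation with fog).

Coordinates are 0-based, x increasing east, y increasing north; actions
are N, E, S, W in that fixed order (used for deterministic iteration and
tie-breaks everywhere). Raw continuous trajectories are out of scope:
grid paths are the input unit, and the synthetic-data generator emits
them directly.

## The two learners

**Model-based (MB).** The learner maintains a transition belief
$T(s,a) \in [0,1]$, the probability that the cell intended by action $a$
from state $s$ is open. In `visual_haptic` it is the true binary map; in
the learned-map conditions it starts at a uniform prior $p_0$ on all
in-bounds pairs and moves toward each observation $h \in \{0,1\}$ by a
learning rate $\alpha$, applied to *every* in-bounds pair leading into
the interacted cell (the spatial inference that a cell open from one
side is open from all sides). The reward function is $R(s,a) = 1$ iff
the pair leads to the target. Before each step the learner plans
offline: value iteration solves
$V(s) \leftarrow \max_a T(s,a)\,[R(s,a) + \gamma V(s')]$ with the target
treated as terminating (its outgoing pairs masked to zero on a
planning-time copy, so learning continues on the unmasked belief), and
the policy is a Boltzmann softmax with temperature $\tau$ over the
bracketed action values.

**Model-free (MF).** A Q-learner with accumulating eligibility traces:
$Q$ starts at zero for all pairs (pessimistic initialization, which
makes previously rewarded sequences self-reinforcing), the trace decays
by $\gamma\lambda$ and gains $+1$ at the taken pair
(decay-then-increment), and a single scalar reward-prediction error
$\delta = r + \gamma \max_{a'} Q(s_{t+1}, a') - Q(s_t, a_t)$ updates all
pairs in proportion to their trace. Block contacts never touch $Q$ or
the trace — the learner has no transition model — and the $\max$ at the
next state ranges over all four in-bounds actions, since a belief-free
learner cannot exclude blocked moves. $Q$ is cleared at each new maze
(the "reset" carryover, which fits behaviour better than inheriting
values); the trace is cleared at each new trial.

## Hybrid mixtures and EM

Each step's action is attributed to exactly one learner; the MF weight
$w_t$ is the prior probability it was the model-free one. Three weight
structures are supported: constant (`hc`, $w = \sigma(b_0)$),
trial-logistic (`hd`, $w_t = \sigma(b_0 + b_1 x_t)$ with $x_t$ the raw
1-based trial index within the maze, uncentred), and free per step
(`hs`). Fitting is by EM on the observed-data log-likelihood
$\sum_t \log[(1-w_t)\,p_t^{MB} + w_t\,p_t^{MF}]$, where the per-step
probabilities are computed *teacher-forced*: the learners are evolved
through the participant's actual recorded events, and probabilities are
renormalized over the actions leading to reachable states.

The E-step computes responsibilities
$q_t = w_t p_t^{MF} / [(1-w_t)p_t^{MB} + w_t p_t^{MF}]$. The weight
M-step is closed-form for `hc` ($b_0 = \mathrm{logit}(\bar q)$), a
fractional-response logistic regression on trial for `hd` (solved by
IRLS via `stats::glm`; its Bernoulli score equations are exactly the
weighted-likelihood condition), and a copy $w_t \leftarrow q_t$ for
`hs`. The learner M-steps maximize the responsibility-weighted
log-likelihoods with the same bounded optimizer as single-model fitting,
warm-started at the previous iterate with two jittered restarts.
Initialization: all weights at 0.5 and learner parameters from
independently fitted single models. Convergence: relative log-likelihood
change below $10^{-4}$, capped at 200 iterations.

Responsibilities are clamped to $[10^{-6}, 1-10^{-6}]$ before logits so
the `hc`/`hd` weight updates stay finite; per-step probabilities are
floored at $10^{-12}$ before logs (floored steps are counted and
reported on fits). BIC is $2\,\mathrm{nll} + k \ln n$ with $n$ the
per-participant number of executed-step likelihood terms; it is not
defined for `hs`, whose per-step weights are a latent vector rather than
parameters.

## Fitting machinery

The optimizer contract is derivative-free bound-constrained
minimization: parameters are mapped to the real line by a logistic box
transform and minimized by Nelder–Mead, best of 10 restarts drawn
uniformly within bounds (restart objective values are kept as a
flat-landscape diagnostic). Bounds: $\alpha, \gamma, \lambda, p_0 \in
[0.01, 0.99]$ and $\tau \in [0.005, 5]$ — wide enough to be
uninformative while keeping the softmax finite and learning
non-degenerate. The Visual-Haptic MB learner exposes only
$(\gamma, \tau)$; the learned-map MB learner adds $(\alpha, p_0)$; MF
always exposes $(\alpha, \gamma, \lambda, \tau)$.

Within a step, the likelihood term is evaluated on the belief state as
of the start of the step (planning runs before each online step); the
step's contact events and the entry observation then update $T$ in
recorded order. Contact order within a step therefore only matters
through $T$, and since all of a step's contact updates move distinct (or
identical) cells toward fixed observations, the likelihood is invariant
to permuting them — a property the tests assert.

### Numerical choices

* Value iteration: synchronous sweeps, sup-norm tolerance $10^{-6}$
  by default, 1000-sweep cap, non-convergence is an error carrying the
  residual. The unique fixed point does not depend on the
  initialization, so the planner warm-starts each re-plan from the
  previous step's values and skips re-planning entirely while the belief
  is unchanged (always the case in `visual_haptic`); direct calls
  default to a zero start. Closed-form checks against $\gamma^{d-1}$ on
  the open maze are run at tolerance $10^{-12}$, because a cell 14 steps
  out has value below the default tolerance when $\gamma = 0.3$.
* Softmax: max-subtracted exponentials; equal values give exactly
  uniform probabilities.
* Eligibility traces: lazy global decay with an active-pair list, with
  renormalization guarding underflow for very small $\gamma\lambda$.
* The compiled replay and simulation cores are cross-checked in the test
  suite against an independent R composition of the exported
  single-event operations, at tolerance $10^{-7}$.

## Autonomous simulation

In closed-loop simulation the agent learns from outcomes of its own
sampled actions: the (possibly mixture-combined) policy is taken over
*in-bounds* actions; a draw into a block is recorded as a contact, the
MB belief is updated toward "blocked" in learned-map conditions, and the
original distribution is renormalized over the remaining options and
redrawn — values are not recomputed mid-step, but the contact update
makes the planner re-plan before the next full step. Trials cap at 88
steps. `hc`/`hd` agents use their parametric weight schedule; the
step-wise `hs` model is descriptive rather than generative, so its
simulation uses a per-trial mean weight. Performance is summarized by
two scaled indices per trial position: success between random-agent
performance (0) and certain success (1), and path length between the
shortest possible length (0) and the expected random-agent length (1).
Indices are reported unclamped (an agent can be worse than random);
positions where the baseline is degenerate yield `NA` with a warning.
The random baseline is a Monte-Carlo estimate (1000 repetitions per
maze-start pair by default, seeded); the tests verify it against an
exact absorbing-Markov-chain solve on small mazes.

## The synthetic-data generator

No behavioural recordings ship with the package, so every pipeline stage
is exercised on synthetic cohorts with known ground truth. Defaults
mirror the study design: 18 participants per condition, a shared ordered
set of 25 solvable 10 × 10 mazes, 10 trials per maze from distinct start
cells to a fixed target, 88-step cap. Mazes are rejection-sampled at a
block-density target of 0.25 (the corridor-style maze sets used in such
experiments are generally not available as bitmaps, so this density is
a documented guess), with the target required to be reachable from
every start. Ground-truth agents
reuse the simulation protocol exactly, so haptic cohorts contain
realistic contact events while visual-haptic planners contact rarely.
Default true parameters — MB $\gamma = 0.9$, $\tau = 0.05$ (plus
$\alpha = 0.5$, $p_0 = 0.5$ when the map is learned), MF $\alpha = 0.5$,
$\gamma = 0.9$, $\lambda = 0.7$, $\tau = 0.05$, schedule $b_0 = -1$,
$b_1 = 0.2$ — were chosen once as values a behavioural-RL practitioner
would call realistic: a sharp-but-noisy softmax, moderate learning
rates, and a weight schedule rising from ≈0.31 to ≈0.73 across ten
trials — a slope magnitude (0.2) typical of a gradual but reliable
strategy shift over ten trials. Optional per-step durations follow a gamma
model whose mean is linked linearly to the true MF weight (default
slope −0.8 s per unit weight), so the weight–speed analysis has a known
planted effect.

What the generator does *not* emulate: continuous kinematics and their
discretization artifacts, within-participant parameter drift,
lapses/attention effects, and any maze structure beyond random block
placement at the target density (real experimental mazes are typically
hand-designed corridor configurations). Passing recovery tests therefore show the
estimator is consistent under the model's own assumptions — not that
real behaviour satisfies them.

## Verification scales and what they showed

The test suite runs, among others: a 50-maze value-iteration oracle
comparison at $10^{-10}$; EM monotonicity and the exactness of the
mixture lower bound (the weighted complete-data term minus
$\sum_t D_{KL}(q_t\|w_t)$ equals the log-likelihood at the E-step
posterior) on 10 seeded cohorts of 5 mazes × 10 trials for all three
hybrid structures; slope-sign recovery on 45 participant-level cohorts
at the full 25 × 10 study scale across $b_1 \in \{0.1, 0.2, 0.4\}$, and
5 six-participant null cohorts whose across-participant confidence
interval must cover zero; a 15-dataset BIC model-recovery confusion
matrix over MB/MF/HC generators; and byte-identical reruns of the
seeded generate → fit → simulate → report pipeline. These sizes were
chosen as the smallest that give the checks statistical teeth.

Two honest findings from these checks are worth knowing about:

* **A residual MF share on pure-MB data.** Fitting the constant-weight
  mixture to data generated by the planner alone settles at a weight of
  roughly 0.13–0.16, not zero: the Q-learner imitates the planner's
  repeated solutions and resolves the planner's exact value ties on
  revisited states, so a small MF share is genuinely likelihood-optimal.
  Mixture weights near zero should therefore not be over-interpreted;
  BIC model comparison still classifies such data as MB.
* **A small positive bias of the null trial-slope.** When the true
  weight schedule is flat, the fitted `hd` slope averages about +0.03
  (with an across-participant spread of similar size) rather than zero,
  robustly to the EM stopping tolerance. With a low true weight and only
  ten trial levels, noisy step-wise responsibilities map onto the trial
  covariate asymmetrically. BIC still favours the constant-weight model
  on such data, so model selection is unaffected; but small positive
  fitted slopes, on their own, should not be read as evidence of a
  strategy shift.
* **Cache-led agents are not doomed in permeable mazes.** At the default
  density, an undirected walk reaches the target within the step cap
  about 30% of the time, and an MF-only agent that caches any successful
  corridor climbs to a success index of ≈0.3–0.4 by trial 10 — well
  above the near-random level the motivating experiments report for
  their (unpublished, corridor-style) maze set. The separation between
  planner-led and cache-led agents is qualitative, not absolute, and
  depends on how hostile the environment is to unguided exploration.

## Known limitations

* The `hs` structure is fitted per step and is descriptive; its BIC is
  undefined and its simulation uses the per-trial-mean approximation.
* Visit counts for the familiarity covariate accrue across trials within
  a maze and include the current entry; the convention is documented and
  deliberate, but other conventions exist.
* The HD inner logistic fit weighs every step equally, so long mazes
  contribute more steps to the weight schedule than short ones.
* Inferential statistics on the exported tables (mixed-effects beta
  regressions, t-tests, ANCOVA) are intentionally out of scope; the
  report module emits analysis-ready long tables instead.
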