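---
title: "Models, fitting and interpretation in cogrnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, fitting and interpretation in cogrnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cogrnn` treats every behavioural model — classical cognitive model or tiny
recurrent network — as the same kind of object: a set of *dynamical
variables* carried across trials, updated by each trial's outcome
(previous action `a`, second-stage state `s`, reward `r`), and read out
into a softmax policy over the next trial's actions. This note documents
the modelling assumptions, the numerical choices, and what the synthetic
data used in the tests do and do not establish.

## The model classes

**Cognitive models.** The catalogue (see `cognitive_catalogue()`) spans
three families. *Bayesian inference* tracks the posterior probability of a
latent "which option is rich" state, combining the likelihood of each
outcome under an emission probability `p_emit` with a per-trial switch
probability `p_r`; the policy applies the softmax directly to the belief
pair `(b, 1 - b)` scaled by an inverse temperature, so the reachable logit
range is bounded by `beta` — a genuine property of this parameterization,
not a numerical artefact. *Model-free RL* updates action values by reward
prediction errors, in anticorrelated (`Q(A1) = -Q(A2)`) or independent
form, with optional forgetting of unchosen values (to zero, or to the
initial value 1/2), perseveration traces, drift-to-the-other updating,
reward-as-cue augmented states, utility/reference-point reward transforms,
and the transition-reversal task's motor-level and multi-trial
perseveration components. *Model-based RL* learns second-stage state
values and computes first-stage action values through the transition
model, either known or itself learned with forgetting toward 0.5.

Two parameterization conventions coexist across the model family definitions
and both are kept: the reversal-task forgetting parameter `D` is a
retention factor (`Q <- D * Q`), whereas the transition-reversal
components' `f_Q`, `f_T` are forgetting rates (`Q <- (1 - f_Q) * Q`). The
motor-level value update backs up `V(s_{t-2})`, the value of the state
*before* the motor context, as that model family defines it.

**Recurrent models.** Three architectures share one contract. The vanilla
GRU consumes a numeric input vector (action, state, rescaled reward; one-
hot actions for more than two arms). The switching GRU treats the discrete
trial outcome as a selector: each of the 4 (reversal) or 8 (two-stage)
input conditions owns its own recurrent weights and biases. Any vanilla
GRU maps exactly onto a switching GRU by absorbing the input projection
into the per-condition biases — `gru_to_switching()` implements this, and
the equivalence is asserted to 1e-10 in the tests. The switching linear
network drops the gates entirely (`h' = W^(x) h + b^(x)`, optionally with
symmetric `W`). One-unit models default to the switching GRU and larger
models to the vanilla GRU, the configuration that predicts best in
practice. The readout is linear with **no bias**, so the policy logit is a
function of the hidden state alone and phase portraits are well defined;
two output scores plus a softmax are used rather than a single logistic
unit. The hidden state starts at 0 at each session (or training-block)
boundary, and the trial-1 policy is read from that zero state.

## Fitting

All models minimize the same loss: the sum over sessions and trials of
`-log Pr(a_t | past, model)`, with missing trials excluded (they keep
placeholder codes and produce no state update) and probabilities floored
at 1e-12 purely as a numerical guard. For the original two-stage task each
trial contributes both choice stages.

*Networks* train with full-batch Adam (learning rate 0.005), an L1 penalty
on recurrent weights (hyperparameter grid `1e-5 … 1e-1`), and early
stopping: the returned weights are from the epoch with the lowest
validation loss, with patience 200 epochs. Weights initialize uniformly on
`(-1/sqrt(d), 1/sqrt(d))`; the random seed is itself a hyperparameter.
*Cognitive models* have no early stopping; they are fitted by BFGS on
smoothly reparameterized parameters — logistic maps for rates and
probabilities, softplus for inverse temperatures, `0.5 + 0.5 * logistic`
for emission probabilities — with random restarts, so every model uses the
same gradient machinery and bounds are enforced without constraints.

*Nested cross-validation* divides sessions into blocks of about 150
consecutive trials (a trailing fragment shorter than half the target
merges into its predecessor; blocks never span sessions), deals the blocks
into ten folds (shuffled once by the seed, then round-robin), and walks
the standard outer/inner loops: one fold out for testing, the inner loop
holding out one of the remaining nine for validation per hyperparameter
setting. The inner winner is chosen by trial-weighted likelihood on the
nine held-in folds, and the final score is the trial-weighted mean over
test folds. For hyperparameter-free deterministic fits the procedure
collapses to plain 10-fold cross-validation; `fit_config(inner_val_folds =)`
exposes that collapse as an efficiency knob, used by the test suite.

*Interspersed splits* for single-block human-style data sample disjoint
train/validation/test index sets of exact sizes (for example 120/20/20 of
a 160-trial block); the whole sequence is always fed to the model and only
the losses are restricted, so all three sets share one trial distribution.

*Dimensionality.* `estimate_dimensionality()` declares d\* to be the
largest hidden size whose model significantly outperforms every smaller
one (paired one-sided t-tests over outer folds, level 0.05, no
multiple-testing correction); this simultaneously satisfies "d\* beats all
smaller d" and "no larger d beats all smaller models". When nothing beats
anything, d\* is the smallest candidate.

## Knowledge distillation

The teacher is a 20-unit vanilla GRU over all subjects: each subject's
one-hot id passes through a trainable linear layer into an embedding
appended to every trial's input. Students are ordinary tiny networks
trained to match the teacher's per-trial action probabilities (the
cross-entropy `-sum_t sum_a pT log pS`, no temperature) on the target
subject's data, augmented fourfold by flipping actions and/or second-stage
states — a symmetry of the two-stage tasks. The teacher itself trains on
raw, unaugmented data so that idiosyncrasies such as side biases remain
learnable and can be transferred; the package's tests verify the
mechanism: augmented data are exactly action-balanced and make the true
side unidentifiable, while a raw-trained model prefers it strongly. The
split discipline follows the M/O scheme: 25% of the target subject's
trials are held out for testing; the rest (optionally subsampled to a
given size) splits 90/10 into training/validation, as does the other
subjects' data; the teacher never sees the held-out trials (asserted at
run time). Teacher embedding width is selected on the target subject's
validation trials; the teacher reuses the network L1 grid.

## Interpretation

For one-dimensional models the policy logit
`L(t) = log Pr(A1)/Pr(A2)` fully characterizes the state, and each input
condition defines a map `L -> L'`. `phase_portrait()` sweeps `dL = L' - L`
along a logit grid and scatters the observed trials; with data supplied,
the grid spans the 0.5–99.5 percentile range of the observed logits, since
portraits beyond visited states are extrapolation. Fixed points are found
by sign-change bracketing plus bisection to `|dL| < 1e-8` on a 512-point
grid, and classified stable when `-2 < g'(L*) < 0` with a central-
difference derivative; an interval with no sign change simply yields no
fixed points. Setpoints iterate one input to convergence (cap 1e4
iterations) from a configurable start — any start in the basin gives the
same limit — and normalize by the largest absolute fixed point so
`max |u_I| = 1` whenever any fixed point is nonzero. The effective
learning rate is the negative secant slope `-g(L)/(L - L*)`, reducing to
`-g'(L*)` at the fixed point and to the constant `alpha` for
prediction-error models. For two-unit models `vector_field_2d()` draws
one-step arrows on the preference plane (readout-scaled hidden units, or
`beta * Q`); for any dimensionality `dynamical_regression()` fits each
coordinate's one-step change on all current coordinates (plus the
continuous reward where the task has one), separately per input condition
with an intercept, assembling the slopes into the input-dependent
state-transition matrix `A`. Conditions with fewer than `d + 2` usable
transitions or a rank-deficient design are flagged rather than estimated.
For model-free RL generators these regressions reconstruct the one-step
map exactly, which the tests assert to numerical precision.

## Task-optimized agents

The meta-RL environment splits each two-stage trial into Delay 1, Go and
Delay 2 periods; non-fixation during delays (or fixation at Go) costs
-0.1, second-stage reward probabilities 0.8/0.2 switch with probability
0.025 per trial, and observations carry the current state, a fixation/go
cue, and the previous step's reward and action. The agent is a 48-unit GRU
core with a 3-way actor head and a scalar critic, trained by advantage
actor-critic. A plain GRU replaces the LSTM often used for such agents: it
keeps the agent Markovian in its hidden state (so the interpretation tools
apply directly) and the analyses consume only input-to-policy behaviour,
which the core choice does not affect. The algorithm's settings are not
dictated by anything external, so they are package defaults chosen from
training curves during development: learning rate 3e-3, discount 0.9,
policy/value/entropy loss weights 1/0.5/0.01, 100-trial episodes, gradient
norm clipped at 5, and a default budget of 2e5 trials. On this
configuration the closed-form reward baselines are 0.5 (chance) and 0.68
(oracle); trained agents reach roughly 0.63-0.66 per trial when sampled,
comfortably above the 0.55 mark the test suite requires after its reduced
1.5e5-trial budget.

## Synthetic data: what it shows and what it does not

All tests run on data from the package's own simulators, under fixed
seeds. The simulators reproduce the tasks' *generative structure* —
reward and transition probabilities, block-switch rules (fixed reversal
windows, per-trial switch hazards, moving-average thresholds with 10- or
20-trial delays, neutral-block hazards, the 9-of-10 win rule, reflected
random-walk drifts) — and the test suite checks those statistics against
their configured values at three binomial standard errors. Two pieces are
deliberate modelling choices where no canonical form exists: the four-armed
bandit's drift schedules are reflected Gaussian random walks on \[0, 100\]
(step s.d. 4) rather than any particular empirical schedule, and the
three-armed task's best-option switch uses a sliding window of the last
ten outcomes on the current best arm. Synthetic subjects are sampled
cognitive agents (for example, 20 learners with learning rates uniform on
0.2-0.8 and inverse temperatures on 2-5 for the distillation study, 400
trials each, matching typical human session sizes).

Passing these tests therefore establishes internal correctness —
equations implemented as defined, recovery of known generators, split
discipline without leakage, interpretable readouts that match algebra —
but not that real animals or humans are well described by any particular
model: real data add slow drifts, lapses, session effects and individual
quirks that no synthetic population here emulates.

## Problem sizes in the shipped tests

The test suite keeps every study at desk scale: 1e5-trial simulations for
rate checks; 1e4 trials for cognitive-model recovery; 3e4 trials for the
one-unit network's likelihood-matching check (2,600-epoch cap); 9,000
trials and ten folds for the dimensionality study (single inner round and
one L1 value, the collapsed form above); 20 subjects x 400 trials and ten
seeds for the distillation comparison; 1.5e5 trials for agent training.
These sizes are the package's chosen defaults for its own verification and
are stated here so that users scaling up know which knobs were reduced.
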