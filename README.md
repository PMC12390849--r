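# cogrnn

Tiny recurrent neural networks and classical cognitive models for
trial-by-trial choice data.

`cogrnn` is for researchers who model reward-learning behaviour — reversal
learning, two-stage bandits, drifting bandits — in animals, humans or
artificial agents, and who want to go beyond hand-crafted cognitive models
without giving up interpretability. The package provides, in one place:

* **Task simulators** for six classic paradigms (two-action reversal
  learning with fixed or performance-triggered block switches, the reduced
  and original two-stage tasks, the transition-reversal two-stage task,
  three-armed reversal learning, the four-armed restless bandit) plus a
  three-period two-stage environment for task-optimized agents.
* **A catalogue of 37 classical cognitive models** — Bayesian inference,
  model-free and model-based reinforcement learning and their forgetting,
  perseveration, utility and mixture variants — each expressed as a
  per-trial state update plus a softmax policy.
* **Tiny recurrent choice models**: vanilla GRUs, switching GRUs (one set
  of recurrent weights and biases per discrete input condition) and
  switching linear networks, with 1–20 units, trained by Adam with L1
  regularization and early stopping (backpropagation through time runs in
  compiled code).
* **Fitting machinery**: the trial-summed negative log-likelihood
  `L = -sum_n sum_t log Pr(a_t | past, model)`, nested cross-validation
  over ~150-trial blocks, interspersed and cross-subject split protocols
  for sparse human data, and a statistical estimator of the behavioural
  dimensionality d\* (the smallest number of dynamical variables that
  optimizes predictability).
* **Knowledge distillation**: a 20-unit teacher with per-subject
  embeddings trained on pooled data, distilled into one-unit students per
  subject by matching the teacher's action probabilities
  (`-sum_t sum_a pT log pS`), with fourfold symmetry augmentation.
* **Dynamical-systems interpretation** of any fitted model: phase
  portraits of the policy logit `L(t) = log(Pr(A1)/Pr(A2))` and its
  one-step change, fixed points with the discrete-map stability criterion
  `-2 < g'(L*) < 0`, normalized preference setpoints `u_I = L*_I / max|L*|`,
  effective learning rates, two-dimensional vector fields, and dynamical
  regression (per-input linear approximation `dP_i ~ b0 + A P (+ b_R r)`).
* **A meta-RL agent**: a 48-unit recurrent actor-critic trained with
  advantage actor-critic on the two-stage environment, whose behaviour can
  be fed back through the same fitting and interpretation tools.

## Worked example

Simulate a model-free learner on the two-stage task, fit a one-unit
switching GRU to its choices, and read the fitted network's phase portrait:

```r
library(cogrnn)

cfg <- task_config("two_stage")            # 0.8/0.2 transitions and rewards
gen <- cognitive_model("mf1", cfg)         # anticorrelated values, d = 1
dat <- simulate_task(cfg, cognitive_agent(gen, c(alpha = 0.5, beta = 3)),
                     n_trials = 20000, seed = 21)

spec <- rnn_spec(cfg, d = 1)               # one-unit switching GRU
fit <- train_rnn(spec, dat, train_idx = 1:14000, val_idx = 14001:16000,
                 fit_config(l1_grid = 1e-5), seed = 1)

nll <- function(tr) negative_log_likelihood(tr, dat, 16001:20000)$nll_per_trial
nll(rnn_policy_trace(spec, fit$weights, dat))
#> [1] 0.2321114
nll(run_cognitive(gen, c(alpha = 0.5, beta = 3), dat))
#> [1] 0.2298825
```

The held-out negative log-likelihood of the fitted network (0.2321
nats/trial) matches the generating model's own score (0.2299) to within
0.003 nats: the one-unit network has recovered the strategy. Its portrait
makes the strategy visible:

```r
pp <- phase_portrait(gen, c(alpha = 0.5, beta = 3), cfg, grid_range = c(-8, 8))
pp$fixed_points[["A1,S1,R=1"]]
#>   L_star slope stable
#> 1      6  -0.5   TRUE
```

Under repeated rewarded choices of action 1, the preference logit is
attracted to `L* = 2*beta = 6` with constant effective learning rate
`-slope = alpha = 0.5` — the model-free signature (a Bayesian learner shows
curved portraits and no attractor at indifference).

## Command line

A thin CLI for the common operations lives at `inst/cli/cogrnn.R`:

```sh
Rscript inst/cli/cogrnn.R simulate --task two_stage --trials 1000 --out s.csv
Rscript inst/cli/cogrnn.R fit --model mf1 --data s.csv --task two_stage \
    --protocol nested_cv --out report.csv
```
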