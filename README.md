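# striatnet

Corticostriatal network models of oculomotor sequence learning: a joint
recurrent-network model of the dorsolateral prefrontal cortex (dlPFC) /
dorsal striatum (dSTR) circuit, the sequence-learning task it is trained
on, and the population-dynamics analyses that show how learning reshapes
its activity space.

## The problem

In the oculomotor sequence task, a subject executes one of eight
three-movement saccade sequences; the correct sequence stays fixed for a
block, a wrong decision forces a repeat of that decision, and the block
ends after eight error-free trials, whereupon the sequence switches.
Behavior sits at chance (~50%) on the first decisions after a switch and
climbs to ~90% correct by the fifth trial. The scientific question is how
this within-block learning is expressed in neural population dynamics
across the corticostriatal circuit.

`striatnet` is for computational neuroscientists who want to simulate,
train, probe, and extend this model class:

* **Task + behavior** — a deterministic task state machine plus a
  Q-learning behavioral model,
  `Q(a) <- Q(a) + α [r + γ max Q(a') − Q(a)]`, softmax choice
  `p = softmax(βQ)` and per-decision decay `Q <- τ_Q Q`, with fitted
  defaults α = 0.8100, γ = 0.2010, β = 3.050, τ_Q = 0.95 and
  maximum-likelihood fitting (`fit_qlearning()`, Nelder–Mead with
  restarts).
* **Networks** — coupled striatal (value-coding) and prefrontal
  (action-selection) tanh rate networks,
  `τ ẋ = −x + W_rr tanh(x) + W_ir u + η`, readouts from synaptic currents,
  trained jointly by exact backpropagation-through-time (RcppArmadillo) on
  the squared-error loss with double weight on the striatal term.
* **Closed loop** — autonomous block production: decoded actions and task
  rewards are fed back as striatal input with all weights frozen.
* **Analyses** — demixed PCA with exact marginalization over time ×
  sequence × certainty, latent-trajectory distance and compactness
  statistics, potential surfaces with fixed-point verification and
  Dijkstra minimal paths between sequence attractors, and CCA comparison
  of population datasets (Wilks lambda, Fisher z).

The headline phenomenon the pipeline reproduces at reduced scale:
**learning pushes action-sequence representations apart in activity
space** (and striatal trajectories become more compact), which makes
erroneous action selection progressively less likely.

## Worked example

```r
library(striatnet)
set.seed(1)

log <- simulate_session(1000)   # Q-learning agent, fitted parameters
error_profile(log)
#> Fraction of first-attempt-correct decisions by trial in block:
#>  trial p_correct     n
#>      1     0.488  3000
#>      2     0.876  3000
#>      3     0.922  3000
#>      4     0.932  3000
#>      5     0.931  3000
#>  ...
```

The agent is at chance on the first trial after a switch and above 90%
from trial 3 — the behavioral learning curve the networks are trained to
internalize. Training and probing the (reduced-scale) network system:

```r
cfg <- coding_config(action_pulse_len = 15, gap = 10)
ds  <- build_dataset(log[log$block_id <= 235, ], cfg = cfg, test_blocks = 25)
net <- init_network(130, 100, dt = 2)
net <- train_network(net, ds, train_config(lr0 = 3e-3, n_outer = 6,
                                           iters_per_outer = 100))

test_mse_by_trial(net, ds)       # error peaks on trial 1, decreases after
run <- run_autonomous(net, 100, cfg, record_states = TRUE)
behavioral_curve(run)            # closed loop: ~0.50 on trial 1 -> ~0.7

pop   <- population_tensor(run, "prefrontal")
model <- fit_dpca(pop$X)
Z     <- project_tensor(pop, model, d = 10, sigma = 2)
inter_sequence_distance(Z, split(1:8, pop$hemifield))$curve
path_length_by_certainty(net, model, pop, "prefrontal")$curve
```

Both the within-hemifield inter-sequence distance and the minimal path
length between fixed points increase from the 50% to the 88–91% certainty
level; `centroid_compactness()` on the striatal tensor decreases. See the
vignette (`vignettes/corticostriatal-model.Rmd`) for the model, every
tunable parameter, and the design decisions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the behavioral
reference quantities of the Q-learning agent on the sequence task — the
fraction of correct first decisions immediately after a sequence switch
(t1) and the fraction of correct decisions on the fifth trial after the
switch (t2), both in percent over ≥1000 simulated blocks — and writes
them to the JSON file given by `--out`.
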