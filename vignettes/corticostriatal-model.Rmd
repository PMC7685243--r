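---
title: "A corticostriatal network model of oculomotor sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A corticostriatal network model of oculomotor sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatnet)
```

## The task and the scientific question

Macaques performing an oculomotor sequence task learn, within a block of
trials, which of eight three-movement saccade sequences is currently
rewarded. Each trial is three binary decisions (left/right at the center,
up/down at the chosen side, left/right within the reached hemifield); a
correct decision is rewarded and advances the trial, a wrong one forces a
repeat of the same decision. A block ends after eight error-free trials,
and the correct sequence then switches. Behaviorally the animals sit at
chance on the first decisions after a switch and climb to roughly 90%
correct by the fifth trial.

`striatnet` implements a two-network rate model of the circuit thought to
support this learning — a *striatal* network that tracks action values and
a *prefrontal* network that selects actions — together with the analysis
toolchain (demixed PCA, latent distance statistics, potential surfaces and
fixed points, Dijkstra path lengths, CCA) used to show the headline
phenomenon: **learning pushes action-sequence representations apart in
activity space**, which makes erroneous action selection progressively less
likely.

## The behavioral value model

Choice behavior is modeled with temporal-difference (Q) learning over the
ten movement directions:

$$Q(a_t) \leftarrow Q(a_t) + \alpha\,[\,r_{t+1} + \gamma \max_{a'}Q(a') - Q(a_t)\,],
\qquad p_t = \mathrm{softmax}(\beta Q_t), \qquad Q_{t+1} = \tau_Q\, Q_t .$$

Defaults are the parameters fitted to monkey session data
($\alpha = 0.8100$, $\gamma = 0.2010$, $\beta = 3.050$) with the decay
fixed at $\tau_Q = 0.95$. `fit_qlearning()` reproduces such fits by
Nelder–Mead simplex search (the R analogue of `fminsearch`) on the choice
log-likelihood, with random restarts in an unconstrained
reparameterization.

Design choices the model leaves open, and how this package resolves them:

* **State space.** One value per movement direction; the availability mask
  of the task (only two options exist at any decision) supplies the state
  structure, and the terminal transition after the third correct decision
  of a trial bootstraps zero. This matches the 10-dimensional value coding
  used by the network model.
* **Reward magnitude** is 1 for a rewarded decision, 0 otherwise.
* **Decay grain.** $Q_{t+1} = \tau_Q Q_t$ is applied once per decision,
  after the update (including on forced repeats). A per-time-step decay
  would confound the decay constant with the pulse geometry of the network
  coding; per-decision is the grain at which the behavioral data are
  sampled.
* **Block switching.** The correct sequence is drawn pseudorandomly and
  *uniformly over all eight sequences* at a block boundary. A draw that
  excludes the previous sequence sounds closer to the word "switch", but it
  makes a value-carrying agent systematically *below* chance on the first
  decision (it perseverates on the old first move, which exclusion makes
  wrong 4/7 rather than 1/2 of the time, giving ≈43% correct). Only the
  uniform draw reproduces the observed 50% chance level at block start —
  by the left/right symmetry of the sequence set it gives exactly 50% in
  expectation — so it is the default; `allow_repeat = FALSE` restores
  exclusion.

The synthetic-behavior generator (`simulate_session()`) is this Q agent
playing the task with the fitted parameters; its learning curve (~50% on
trial 1, >90% from trial 3 on, flat thereafter) is the package's stand-in
for the animals' error profile, exactly the role artificial blocks played
for data augmentation in the original training sets. A `parametric` mode
draws correctness from an explicit per-trial probability profile instead,
so the analyses can be stress-tested at arbitrary learning rates. What the
generator does *not* emulate: session-to-session drift, reaction times,
fixation breaks, or any stimulus-driven (color-bias) choices — a green test
against this generator validates the machinery on a stationary, idealized
learner, not on monkey idiosyncrasies.

## Signal coding

`encode_block()` turns a block of decisions plus its value traces into
network tensors. A block with $D$ decisions becomes $D+1$ segments of
`gap + action_pulse_len + reward_pulse_len` time steps:

* the striatal input (15-D) replays each decision as a unit-amplitude pulse
  on its direction channel, followed by a reward pulse on the channel of
  the decision point where the reward was delivered (center /
  upwards / downwards / upper / lower). The reward pulse starts exactly at
  the end of the action pulse and lasts 2/10 as long;
* segment 0 carries the white-noise action input (SD 0.01) that opens a
  block;
* the prefrontal instruction input (10-D, a Fixate and a Move+Hold channel
  per decision point) marks the *upcoming* decision: its Fixate channel is
  on during the gap, its Move+Hold channel during the action pulse. At the
  second movement both the upwards and downwards target channels are shown
  (both targets are visible; lighting only one would leak the correct
  choice), and at the third the channel of the hemifield actually reached;
* the striatal target (10-D) holds the Q values in force before the
  decision until reward onset and the updated values afterwards
  (zero-order hold; linear interpolation available);
* the prefrontal target (11-D) is the action pulse of the *next* decision
  plus a hemifield unit at ±1 throughout the block.

Pulse durations are not dictated by the physiology beyond the 2/10
reward-to-action ratio; the defaults (50-step action pulse, 10-step gap,
1 ms steps with a 10 ms time constant) put a decision at 70 network time
constants /10 — long enough for the recurrent state to integrate each
event. The 10-step gap doubles as the fixation period used by the
fixed-point verification. Tests and examples use shorter pulses (e.g. 15/3/10)
purely for speed; all ratios and amplitudes are unchanged.

## The network system

Both networks are tanh rate networks integrated by explicit Euler
($dt/\tau = 0.1$),

$$\tau \dot x = -x + W_{rr}\,\tanh(x) + W_{ir}\,u + \eta,$$

with readouts taken from the synaptic currents, $u_v = W^s_{ro} x_s$ and
$u_a = W^p_{ro} x_p$. The striatal readout (10-D action values) is joined
with the instruction channels to form the prefrontal input; this readout
coupling is the only connection between the two networks. Reference sizes
are 1300 striatal and 1000 prefrontal units; recurrent weights are
i.i.d. normal scaled by $g/\sqrt{N}$ with $g = 1$, and every unit receives
independent white noise of SD 0.01 inside the Euler update. Input and
readout weights are scaled by the reciprocal square root of their *true*
fan-in (15 and 20 for the inputs) — printed scaling denominators of 20 and
510 appear in the source description but are inconsistent with the stated
input dimensionalities, so actual fan-in is used.

Training minimizes the joint squared error
$\;l = 2\sum_k\sum_t\sum_i (\hat y^v - y^v)^2 + \sum_k\sum_t\sum_i (\hat y^a - y^a)^2\;$
(double weight on the striatal term, plain sums, no averaging) over batches
of 10 blocks drawn with replacement, with exact backpropagation-through-time
gradients (hand-derived, implemented in C++, verified against central
finite differences to $10^{-4}$ relative error). The reference schedule is
an initial rate of $10^{-3}$ for 10 outer steps of 1000 iterations, the
rate multiplied by 2/3 at each outer step — "decayed by 2/3" being the only
reading of the printed schedule consistent with a decaying rate. The
optimizer is Adam; only the schedule and the use of automatic
differentiation are dictated by the source description, and plain SGD is
available by configuration. Error decisions stay in the training set with
the executed (wrong) action as the target, so the system learns the
behavioral error statistics rather than an idealized perfect policy.

## Autonomous mode

After training the weights are frozen and the loop is closed
(`run_autonomous()`): each decision's action pulse and reward pulse are fed
back into the striatal network, its value readout drives the prefrontal
network together with the upcoming stage's instructions, and the next
action is decoded by sampling a softmax over the action-channel outputs
averaged across the action epoch, restricted to the two options available
at the current stage. The decoding temperature deserves a note: because the
prefrontal network is trained on *stochastically* chosen actions, its
least-squares optimum is the conditional mean of a one-hot draw — i.e. its
output amplitudes approximate choice probabilities, not saturated logits. A
unit-temperature softmax over probability-valued outputs can never choose
the better option with more than plogis(1) ≈ 73% probability, flattening
the closed-loop learning curve no matter how well the system is trained.
The decoder therefore defaults to the same inverse temperature that
generated the behavior (β = 3.05): reading out probability-coded outputs
with the generating β reproduces the behavioral curve, which is exactly
what the closed-loop system is supposed to do. Unit temperature remains
available (`decode_beta = 1`). A block opens with white-noise
action input; after an error the reward channels are set to white noise and
the same stage is repeated with unchanged instructions. Synaptic currents
are carried across segments and blocks — the system is never reset within
a session.

## Analyses

**Population tensors.** Closed-loop activity is averaged over trials into a
units × 8 sequences × 3 certainty levels × time tensor. A trial's time
course is the concatenation of the three segments replaying its
first-attempt decisions, so error trials contribute the same time base as
clean ones. Certainty levels label each trial with the empirical
fraction-correct of its position in the block, binned to the three analysis
levels (≈50%, ≈76%, 88–91%) by nearest level — the binning rule is the
package's choice, as only the levels themselves are stated.

**dPCA.** `marginalize()` performs the exact factorial decomposition
$X = X_t + X_s + X_c + X_{st} + X_{sc} + X_{ct} + X_{noise}$ (checked to
machine precision in the tests), and `fit_dpca()` solves the per-parameter
reduced-rank regression $\min \lVert X_\phi - F_\phi D_\phi X\rVert^2$ in
closed form (ridge-regularized, default $\lambda = 10^{-6}\lVert X\rVert^2$;
regularization is a numerical safeguard the source does not discuss).
Latent trajectories are Gaussian-smoothed (default SD 2 bins, unstated in
the source) projections onto the leading sequence-subspace decoders.

**Distances.** Inter-sequence distances are time-averaged Euclidean
distances between trajectories, within hemifield clusters for prefrontal
data, computed either in full unit space or (for model data, following the
original practice) in a 10-dimensional sequence-dPC space; compactness is
the time-averaged distance of a trajectory to its own time-centroid.
Increases in the first measure and decreases in the second across certainty
levels are the learning signatures.

**Potential surfaces.** A mesh over the top-two sequence-subspace latent
dimensions (bounding box of the two trajectories of interest, padded 25%,
default 60 × 60) is lifted to unit space through the sequence encoder, set
as the firing-rate state ($x = \mathrm{atanh}(r)$, clipped into
$(-1, 1)$), and the network is stepped once with input frozen at a chosen
trial moment and noise off; the surface value is $\lVert\Delta x\rVert$.
Two numerical choices matter here. First, the lift: adding the
sequence-subspace offset to the per-unit *grand mean* alone places mesh
states far off the network's operating manifold, and the one-step change is
then dominated by the restoring drift back to the manifold — the surface is
uniformly steep and featureless. The lift therefore anchors the mesh on the
condition-mean state at the frozen trial moment (`baseline` argument), so
the surface reflects the dynamics in the neighborhood the trajectories
actually occupy. Second, fixed-point verification: trough states are given
10 noise-free iterations to shed the transient induced by the rank-2 lift,
and must then move (in latent projection) less than half the mesh diagonal
over the following fixation period (10 iterations). The reduced-scale
networks exhibit slow drift rather than strictly stationary points, so this
is a stay-within-basin criterion — what the ridge-crossing path analysis
actually requires — rather than pointwise stationarity; the strict
criterion with a tight tolerance is exercised on constructed linear systems
in the test suite. The default frozen moment is mid-fixation before the
first movement — the imaged moment is not stated in the source, and it is
exposed as a parameter. The joint surface of two sequences is the
point-wise minimum; each sequence's trough is located within its own
Voronoi cell of the joint mesh, and `min_path_length()` runs Dijkstra on
the 8-connected mesh graph with edge weights equal to the Euclidean step
length in (latent1, latent2, value) space. A pure-cost alternative (mean
endpoint value × planar step) is available behind a flag; the Euclidean
reading makes the flat-surface oracle exact and is the default.

**CCA.** `cca_compare()` smooths, reduces each dataset to 15 dimensions,
and extracts the first 10 canonical correlations by SVD of the
ridge-whitened cross-covariance; `cca_significance()` provides the
sequential Wilks-lambda tests and `fisher_z_compare()` the z-comparison
between coefficient sets (trained vs. untrained model). The monkey
recordings behind the published coefficient values are not public, so the
shipped experiments compare against model-generated surrogate references;
any units × time matrix can be dropped in instead.

## Scale, runtime, and what the tests establish

The full-scale system (1300/1000 units, 10 × 1000 training iterations on
hundreds of blocks) trains for hours on one CPU. The package therefore
adopts a 5×-reduced default for its executable checks: 260 striatal / 200
prefrontal units, ~200 synthetic blocks, shortened pulses, and a few
hundred Adam iterations. At this scale the qualitative phenomena — test
error concentrated on the first trial after a switch, chance-to-asymptote
behavioral curves in closed loop, sequence representations separating and
striatal trajectories compacting with certainty, and fixed points moving
apart — are reproduced in minutes, and that is what the test suite
asserts. Quantitative values tied to the full-scale system (e.g. the
published CCA coefficients against recordings) are out of reach without
the recordings and are not asserted anywhere.

Numerical notes: rollouts and BPTT are exact reimplementations of the
Euler dynamics (noise is drawn in R, so everything is reproducible under
`set.seed`); the mesh lift clips rates at $\pm(1 - 10^{-6})$ before the
inverse tanh; CCA whitening adds $10^{-8}$ of the mean eigenvalue;
degenerate inputs (empty logs, empty meshes, unbalanced tensors, missing
fixed points) raise informative errors rather than propagating NaNs, and
pairs whose trough fails fixed-point verification are skipped with a
warning rather than fabricating a path.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
log <- simulate_session(300)          # Q agent with the fitted parameters
error_profile(log)                    # ~50% on trial 1, >90% by trial 5

ds <- build_dataset(log, cfg = coding_config(action_pulse_len = 15),
                    test_blocks = 25)
net <- init_network(260, 200)
net <- train_network(net, ds, train_config(n_outer = 5, iters_per_outer = 60))
test_mse_by_trial(net, ds)            # error peaks on trial 1

run <- run_autonomous(net, 100, ds$cfg, record_states = TRUE)
behavioral_curve(run)                 # closed-loop learning curve

pop <- population_tensor(run, "prefrontal")
model <- fit_dpca(pop$X)
Z <- project_tensor(pop, model, d = 10)
inter_sequence_distance(Z, split(1:8, pop$hemifield))$curve
path_length_by_certainty(net, model, pop, "prefrontal")$curve
```

## Known limitations

* No spiking units, no Dale's-law sign constraints, no direct/indirect
  pathway structure: the model is a rate abstraction of the circuit.
* The sequence-id ↔ path assignment beyond the hemifield partition is a
  fixed convention (the exact labeling is not recoverable from aggregate
  statistics); all statistics reported by the package are invariant to it.
* Analyses assume balanced population tensors; heavily error-laden runs at
  very small block counts can leave (sequence × certainty) cells empty, in
  which case more blocks must be simulated.
* The instruction-channel semantics (5 decision points × Fixate/Move+Hold)
  are one consistent reading of a loosely specified cue code; alternatives
  (e.g. stage-indexed channels) would relabel inputs without changing the
  model class.
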