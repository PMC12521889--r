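---
title: "Decoding economic value from prefrontal spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding economic value from prefrontal spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(valdec)
```

# The problem

During value-guided decisions, neurons in the orbitofrontal cortex (OFC)
encode the subjective value of the options under consideration.  `valdec`
implements an adaptive neural decoder that reads out a subject's *choice*
from a multivariate spike-count time series: a tensor of
trials x cells x time bins (12 bins of 50 ms, spanning -200 ms to +400 ms
around the moment the second of two options is viewed), plus a behavior
table giving, per trial, the identity and reward level (1-5 drops) of the
first- and second-viewed stimulus and the recorded choice.

The decoder is trained by offline reinforcement learning rather than
supervised classification: each trial is a state, predicting the chosen
option is an action, and a correct prediction earns reward +1.  This
framing extends naturally to multi-step settings (executing an action
sequence on the user's behalf) and to decision-time settings (committing
to a prediction before the neural evidence is complete), both of which
are implemented here as additional environments.

Because the primate data set this framework was developed against is not
publicly deposited, the package ships a fully specified synthetic session
generator with known ground truth, and every claim the package makes is
exercised end-to-end against that generator.

# The synthetic world

`generate_session()` draws sessions from an explicit generative model:

* **Task.** 12 stimuli, each mapped to a value level 1-5, every level held
  by at least two physically distinct stimuli (so some trials have no
  objectively better option); ordered stimulus pairs drawn uniformly from
  the 132 distinct conditions.
* **Choice.** Each trial draws latent *subjective* values
  $\tilde v_i = v_i + \varepsilon_i$, $\varepsilon_i \sim N(0, 0.7^2)$,
  and the subject picks $\arg\max_i \tilde v_i$.  The jitter SD 0.7 was
  fixed a priori from the behavioral constraint
  $\Phi(2 / (0.7\sqrt 2)) = 0.978 \ge 0.95$: options differing by two or
  more drops are chosen correctly at least 95% of the time, while
  equal-value choices remain variable.
* **Spikes.** Cell $c$ fires Poisson counts per 50 ms bin with rate
  $\lambda_{c}(t) = \max(0,\; b + g_{c,1}\,\tilde v_1\,\kappa_1(t) +
  g_{c,2}\,\tilde v_2\,\kappa_2(t))$, baseline $b = 5$ Hz.  30% of cells
  are untuned.  Crucially, the *same* latent $\tilde v$ drives both the
  choice and the rates, so equal-value trials remain decodable above
  chance — the signature that a decoder reads subjective rather than
  objective value.
* **Kernels.** $\kappa_2$ (second-viewed value) is exactly zero until
  200 ms after second-target viewing and peaks near +300 ms, reproducing
  the known onset latency of OFC value signals.  $\kappa_1$ (first-viewed
  value) is the sum of a weak early bump (amplitude 0.03, peak +50 ms) —
  the decayed remnant of a signal whose peak preceded this analysis
  window — and a strong component with the same late time course as
  $\kappa_2$, reflecting that both offer values are re-expressed while
  the comparison unfolds.
* **Tuning heterogeneity.** Gains are $g_{c,i} \sim N(4, 18^2)$ spikes/s
  per value unit, independent across cells and across the two options,
  with mixed signs (realistic OFC mixed selectivity).  This matters: with
  homogeneous positive gains the two late value signals would occupy
  nearly collinear population directions and their difference would be
  unrecoverable.

Three quantitative anchors were used to calibrate (once) and then freeze
these defaults:

1. the exhaustive likelihood-ratio oracle (below) decodes choice at
   ≥ 0.85 (measured 0.888 over five default sessions);
2. a kernel classifier given only the bins up to second-target viewing
   performs near chance (~0.55), matching the reported behavior of
   supervised decoders truncated at that point;
3. time-resolved linear decoding finds the first value above chance in
   early bins and the second value at chance before +200 ms and strongly
   decodable after.

The generator deliberately omits: biophysical spiking structure,
session-to-session drift, eye movements, LFPs, and noise correlations
beyond those induced by the shared latent values.  A green test on this
world therefore certifies the *pipeline* (preprocessing, training,
masking, forecasting, attribution, uncertainty bookkeeping) and the
qualitative structure it exploits, not quantitative agreement with any
particular monkey.

## The oracle

`bayes_oracle_accuracy()` integrates the Poisson likelihood over a
41 x 41 grid of the two latent values (true gains and kernels known) and
compares the region-normalized likelihoods
$P(\text{spikes} \mid \text{choice} = \text{first})$ vs
$P(\text{spikes} \mid \text{choice} = \text{second})$.  Normalizing each
region by its prior mass means a zero-information session decodes at
chance — the oracle measures what is decodable *from spikes*, not what
the value-level prior alone predicts.  Numerically tied likelihoods are
split deterministically by trial parity.  The oracle upper-bounds any
trained decoder and was used to calibrate the simulator's
signal-to-noise once.

# Preprocessing

Each (cell, bin) feature is z-scored with training-trial statistics and
the training z-range is mapped affinely onto $[-1, 1]$ (the min-max
reading of the two-stage scaling); held-out values are clipped into the
interval, degenerate features map to 0.  Split sizes round half up, so
20% of a 630-trial session yields 126 training trials.  Synthetic
training trials add i.i.d. uniform noise (bound 0.1, clipped) to scaled
trials; the default is one fixed synthetic copy per real trial per run
(the augmentation count is not pinned down by the source description, so
it is a configuration knob).

# The decoder

The core agent embeds each bin's population vector with a linear layer
(d_model = 100), prepends a learned class token, adds sinusoidal
positional encodings, and applies a 2-layer post-LN transformer encoder
(4 heads, feed-forward width 200, ReLU; heads and width are our
smallest-standard choices where the source is silent).  A linear head
maps the class-token output $\chi_1$ to one Q value per action.  A
per-trial key mask restricts attention to a contiguous prefix of bins;
masked bins are provably invisible (no permitted query ever attends to
them), which the suite verifies bit-exactly.

Training follows the standard offline loop: each iteration rolls 5
episodes under a Boltzmann policy ($\tau = 1$) over a without-replacement
sample of training trials, stores (s, s', r, a) tuples in a FIFO replay
buffer, samples K uniformly and takes Adam steps on the squared error
between $Q(s, a)$ and the target $r + g\,\max_{a'} Q(s', a')$.  The
choice environments use $g = 0$ (one prediction per trial, terminal);
the sequence environment uses $g = 0.99$ with a softly updated target
network ($\rho = 0.005$).  We default to Adam with learning rate 1e-3:
with 100-300 total updates, a rate of 1e-4 cannot move the network far
enough from initialization to approach the near-ceiling training
accuracy this architecture reaches (the source states the optimizer but
not the rate).  Everything is seeded; identical configurations reproduce
training logs bit-for-bit.

All neural-network primitives are implemented natively — the transformer
in compiled RcppArmadillo, the recurrent models in batched R — with
hand-derived backward passes.  Every gradient path is verified against
central finite differences in the test suite (worst relative error
~1e-9), which is the correctness backbone of the whole package.

# The forecasting (Internal) module

The forecaster is a variational recurrent model over the scaled activity:
a tanh recurrence $h_t = d_h(\mathrm{concat}(x_{t-1}, s_{t-1}), h_{t-1})$,
a conditional prior $d_z(z_{t-1}, h_t) \mapsto (\mu, \sigma)$ over a
64-dim latent, an inference encoder that additionally sees $x_t$ (used in
training and reconstruction), and a decoder $d_x(z_t, h_t) \mapsto
\hat x_t$ with a Gaussian output likelihood.  Training minimizes the
negative per-step ELBO (reconstruction minus KL between posterior and
conditional prior) summed over bins, teacher-forced, on training trials
only.  The source cites but does not print its ELBO; we follow the
standard formulation with a *learned conditional prior*, which is also
what forecast-time generation requires.

$s_t$ is a frozen 50-dim random tag (entries Uniform(-1, 1)) identifying
each stimulus: the first-viewed tag before second-target viewing, the
vector sum of both tags afterwards; a NOSTIM model receives zeros.

Two prediction modes matter:

* **reconstruct** — teacher-forced everywhere (posterior mean); the
  quality upper bound;
* **forecast** — teacher-forced through the real prefix, then self-fed
  using the prior mean; errors compound with horizon.  The suite asserts
  forecast error ≥ reconstruction error per horizon with a small
  numerical band (0.01): at horizons where the inference encoder adds
  nothing over the prior the two coincide to sampling noise, so a strict
  pointwise inequality is not numerically meaningful.

**Forecast-path standardization.**  Raw forecasts are dominated by
static per-(cell, bin) mean patterns; the choice-relevant part is the
small trial-to-trial variation around them, and the attention stack —
whose positional encodings and layer norms are tuned to full-range
inputs — extracts almost nothing from the raw signal (RL readout ~0.53
held-out, while an OLS probe on the same features reached 0.82).  The
combined agent therefore standardizes forecast-path inputs per
(cell, bin) with training-pool statistics (scaled to sd 0.5, clipped to
$[-1, 1]$) — the same convention the preprocessing applies to real data.
The statistics are stored with the trained agent and reused at
evaluation; held-out trials never contribute to them.

The combined (STIM/NOSTIM) agent runs the core encoder over the real
prefix (core mask) and a second encoder over the forecasted bins
(complementary mask), concatenates the two class tokens, and maps them
with a linear fusion head — the simplest fusion under which "ablating a
path" is well defined as zeroing its representation (`no_core`,
`no_forecast`, and `no_stimvec` = zero tags at test time).  During agent
training the forecaster is frozen; a checksum test enforces this.

# Analyses

* **Representation decoding** — OLS from the 100-dim class-token vector
  (training trials) to first value, second value and their difference;
  out-of-sample $R^2$ on held-out trials.  Decoding uses raw value
  levels with an intercept; OLS $R^2$ is invariant to centering.
* **Time-resolved decoding** — per-bin OLS with 5-fold CV, 10 repeats.
* **Shapley attribution** — expected-gradients estimator (interpolated
  inputs against a background of 50 training trials) of the greedy
  action's Q value; absolute attributions averaged over cells and trials
  and normalized to sum to 1 over bins.  The estimator is held to within
  5% of exhaustive-coalition Shapley on small linear models.
* **Uncertainty** — 5-member ensembles (random initialization for the
  neural decoders, disjoint training partitions for the kernel
  classifier); total uncertainty is the entropy of the member-averaged
  predictive distribution, aleatoric the mean member entropy, epistemic
  their difference (non-negative by Jensen; at most $\ln 2$ for two
  classes).  RL agents contribute Boltzmann probabilities of their Q
  values; ensemble members are fully independent runs (no shared replay
  buffer).
* **Supervised baselines** — a radial-basis-kernel classifier on
  flattened cells x bins vectors and a single-layer tanh RNN (hidden
  100, last state to a linear classifier), trained with labels, no
  augmentation, full-length trials; evaluated by 5-fold CV.  No kernel
  SVM exists in this R stack, so the kernel classifier is fit by
  penalized kernel logistic regression — the uncertainty analysis needs
  calibrated probabilities, which the logistic likelihood provides
  directly.  Truncated-input evaluation replaces post-cutoff bins with
  the same bins from permuted trials (default 1,000 permutations,
  configurable up to 10,000).

# The early-prediction experiment

`run_early_prediction_experiment()` freezes the desk-scale protocol: per
session, train the forecaster (120 epochs), a BASE agent (120 iterations,
2 gradient steps per iteration) and a STIM agent (60 iterations — it
converges faster because the forecast path linearizes the problem, and
longer training only accrues memorization of the finite trial pool) in
the masked environment with uniform random cutoffs; compute held-out
accuracy as a function of the cutoff; set the criterion at the midpoint
between chance and the BASE agent's full-cutoff accuracy; and report how
much earlier (ms, cutoff time = end of the last real bin) the STIM agent
first reaches criterion.  On this world the BASE agent stays near chance
until the second-target latency has elapsed and crosses criterion around
+250..300 ms, while the STIM agent is above criterion from the earliest
cutoffs — its forecasts inherit both stimulus identities through the
tags — giving leads of roughly 400 ms.

# Numerical choices and degenerate inputs

* Attention masking uses additive -1e30 before the softmax; the class
  token is always attendable, so no attention row is ever fully masked.
* LayerNorm uses population variance with eps = 1e-5; post-LN residual
  placement follows the printed equations.
* Forecaster standard deviations are softplus-parameterized with a 1e-4
  floor; KL terms are exactly non-negative.
* Adam uses a global gradient-norm clip of 5 (stability at learning rate
  1e-3; the loop is otherwise warmup-free).
* Degenerate scaler features (zero training SD or constant z-range) map
  to 0; a cutoff equal to the full window yields an empty, valid
  forecast; an all-masked forecast path reduces the class token to a
  learned constant.
* Oracle likelihood ties are split by trial parity (deterministic
  chance).

# Known limitations

* The generator's Poisson independence understates realistic noise
  correlations; decoder accuracies here are optimistic relative to real
  OFC data at matched cell counts.
* The combined agent is occasionally unstable at the single largest
  cutoff (where the forecast path sees one bin or none); this does not
  affect the criterion-crossing analysis, which is anchored at the BASE
  agent's full-cutoff accuracy.
* Sequence-task (value-mapped) performance is limited by how much value
  information survives in choice-optimized representations, mirroring
  the source's own observation; the conservative regularizer weight
  (0.1) is an interpretation, as the cited regularizer is not printed.
* The suite's acceptance runs are desk-scaled (3 choice-decoding and 2
  early-prediction sessions instead of 5); `scripts/acceptance.R` runs
  the full 5-session early-prediction protocol.
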