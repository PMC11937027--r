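---
title: "Detecting anomalous EEG channels by graph correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anomalous EEG channels by graph correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeggca)
```

## The problem and the idea

During an epileptic seizure, some scalp-EEG channels decouple from the rest of
the montage: their signals correlate more weakly with their neighbors than
they do in the normal state. `eeggca` turns that observation into an
unsupervised detector. It never sees seizure data; it learns what *normal*
inter-channel structure looks like, and at test time it flags the channels
whose own-signal content disagrees with what their graph neighborhood
predicts.

Each clip (a fixed 12-second window of the 19-channel 10-20 montage by
default) becomes an attributed graph `G = {A, X}` with one node per channel.
Two parallel views of the same clip are encoded with a **weight-sharing**
variational graph convolutional encoder:

* the **structural view** encodes `{A, X}` — each node aggregates its
  neighbors through the normalized adjacency;
* the **semantic view** encodes `{I, X}` — the identity graph, so each node
  sees only its own features.

Because the two passes share every weight, their embeddings live in the same
space and are directly comparable. For a normal channel the two views agree;
for a channel whose relationship to its neighbors is disturbed they do not.
The anomaly score of channel *i* is the squared distance between its rows in
the two column-normalized embeddings — the per-node share of the invariance
loss — and a clip score is the mean (or max) over channels.

## Graph construction

Six adjacency variants are provided, mirroring the different priors one can
put on inter-channel structure: `dist` (Gaussian kernel of inter-electrode
distance with cutoff `k = 0.9` on unit-sphere coordinates, fixed per cap),
`corr` (normalized cross-correlation of feature rows, sparsified to each
node's top-3 neighbors by absolute weight), `rand` (all 0.5), `full` (all 1),
`dtf` (correlation rescaled by total squared correlation to third channels,
same top-3 support), and `identity`. The correlation dialect is Pearson:
mean-centered dot product divided by the centered norms, one scalar per
channel pair. Top-3 ties are broken toward the lower channel index so graphs
are bit-reproducible.

The feature matrix `X` is deliberately simple: per channel, the
log-magnitude of the first `D = 64` non-DC DFT bins, z-scored per channel
(`raw` mode, a z-scored uniform downsample, is kept as an option). Band-power
profiles are the conventional attribute for EEG graphs and make correlated
channels have correlated feature rows, which is what the `corr`/`dtf`
builders need.

## Encoder, objective, and training

The encoder is one shared hidden GCN layer (`H = relu(P X W1)`, width
`h = 64`) feeding two linear GCN heads producing a per-node Gaussian
posterior (`mu`, `log sigma^2`, dimension `d = 32`). `P` is the symmetric
GCN normalization `D^{-1/2}(A + I)D^{-1/2}`. Two numerical choices matter
here:

* **Degrees use absolute weights.** Correlation graphs are signed; a row's
  signed degree can cancel to nearly zero, which makes `D^{-1/2}` explode
  (we observed propagation weights above 11 and KL terms around 1e23 at
  initialization). Absolute-weight degrees bound the operator and are
  identical to ordinary degrees on nonnegative graphs.
* **Heads output log-variance**, so variances stay positive without
  constraints and the closed-form KL is stable.

The training loss has three parts, equally weighted by default:

* **KL alignment**: the closed-form divergence of both views' posteriors
  from the standard-normal prior, summed over nodes and dimensions. Both
  distributions are pulled to one prior, which keeps the two views on a
  common scale. (The divergence is *minimized*; its sign is chosen so the
  posteriors approach the prior.)
* **Reconstruction**: the fused embedding `Z_f = Z_st + Z_se` is decoded by
  a 2-layer MLP back to `X` and by a logistic-squashed Gram matrix back to
  `A`; the loss is the sum of the two unsquared Frobenius norms. The
  logistic squashing keeps the structure reconstruction in (0, 1), matching
  adjacency semantics and bounding the gradient.
* **Soft-CCA**: after column normalization (subtract column mean, divide by
  the *population* column SD and by `sqrt(N)`, so `t(Z') %*% Z'` is exactly
  the column correlation matrix), an invariance term `||Z_st' - Z_se'||_F^2`
  pulls the views together while a decorrelation term
  `||t(Z') %*% Z' - I||_F^2` (both views, weighted by `lambda = 0.1`)
  prevents the collapsed solution in which all embedding dimensions carry
  the same signal. The `sqrt(N)` scaling is the only convention under which
  comparing `t(Z') %*% Z'` to the identity is scale-consistent.

Optimization is Adam (`lr = 1e-3`) for 200 epochs, one full-batch gradient
step per clip per epoch, with hand-derived analytic gradients; a
finite-difference check in the test suite pins them to 1e-4 relative error.
All randomness (initialization, noise draws, step order) flows from a single
seed, so training is exactly reproducible.

**Training uses posterior means.** The reparameterized sampler
(`Z = mu + sigma * eta`) is implemented, tested, and available via
`gca_config(sample = TRUE)`, but the default objective is evaluated at the
posterior means. With two independent noise draws per step, the invariance
term has a noise floor of about `2d` that no parameter setting can beat, and
the cheapest descent direction is then to collapse both posteriors onto the
prior — which erases exactly the mean structure the test-time score uses. In
our measurements, sampled training left the invariance loss at its chance
level and pushed node-level AUC on the corruption benchmark *below* the
untrained initialization, while mean-based training (same weights, same
`lambda`, same epochs) trains the invariance loss from ~25 to ~7 and scores
AUC ≈ 0.99. The KL term still regularizes the full posterior either way.
Scoring always uses posterior means, so scores are deterministic.

## The synthetic benchmark

Real seizure corpora are access-controlled, so the package ships a generator
that emulates normal EEG *at the level the detector consumes*: each channel
is a nonnegative mixture of `n_sources = 4` band-limited stochastic sources
(band-pass filtered white noise in 1–30 Hz) plus white noise
(`noise_sd = 0.1` relative to unit-variance sources). Sources are placed on
the scalp sphere and mixed with a squared-exponential spatial profile, a
crude stand-in for volume conduction; nearby channels therefore share
sources and correlate positively, giving the correlation graphs realistic
structure. It does **not** emulate seizure morphology, artifacts, 1/f
spectra, nonstationarity, or inter-patient variability — so a passing
benchmark shows the method recovers *the defined corruptions under the
stated correlation structure*, not clinical performance.

The corruption protocol averages every 35 consecutive clips' feature
matrices (no overlap, remainder dropped), builds one graph per averaged
clip, and corrupts each with probability `p_inject`: one uniformly chosen
node is corrupted **both** structurally (connected to all other nodes) and
contextually (its feature row replaced by that of the Euclidean-farthest
node). At most one node per clip is corrupted, and the clip label is the OR
of the node labels. The default `p_inject = 0.03` reflects the intended
rarity of anomalies; the protocol description elsewhere also mentions a
0.03% figure, which would yield essentially no positives at test scale, so
3% per averaged clip is taken as the operative rate and the parameter is
exposed.

## Problem sizes and verification

The shipped verification runs use: 350 normal clips → 10 averaged training
clips; 50 independent corruption replicates at `p_inject = 0.5` (raised so
that ~250 of 9,500 scored nodes are positive); 200 training epochs. At these
sizes the whole train-and-evaluate cycle takes a few minutes on one CPU.
Typical results (seeds 1 and 7): node-level AUC 0.99, average precision
0.79–0.80, specificity 0.95–0.96 at the 95th-percentile-of-normal threshold,
and the injected channel outscoring its clip's median channel in 100% of
corrupted clips; the mean absolute off-diagonal correlation of the embedding
dimensions falls to less than half its initialization value, confirming the
decorrelation term does its anti-collapse job.

## Other design choices and limitations

* The variational heads read the hidden layer `H`, not raw `X`.
* The specificity operating point is the 95th percentile of scores on
  held-out normal data (`choose_threshold`), reported with the threshold.
* Clip-level aggregation defaults to the mean of node scores; max is
  available for localized events.
* `eps = 1e-8` floors every variance, norm and denominator; degenerate
  (constant) channels z-score to zero with a warning rather than NaN.
* The EDF reader covers plain continuous EDF with one sampling rate across
  retained signals — enough for ingestion of standard exports; EDF+ events,
  mixed rates, bipolar re-referencing and artifact rejection are out of
  scope.
* Thresholds, dimensions and epochs were fixed once at the defaults above;
  they are configuration, not fitted quantities.
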