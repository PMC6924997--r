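---
title: "Inverted encoding models: methods, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverted encoding models: methods, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An inverted encoding model (IEM) analyzes a multichannel measurement —
typically trial-wise fMRI voxel activations — through a hypothesized bank of
*feature channels*. For a circular stimulus feature such as visual
orientation (period 180°), the analyst picks `k` channel sensitivity
functions over the feature axis. A trial with stimulus value $\theta$ is
summarized by the predicted channel response vector
$C(\theta) \in \mathbb{R}^k$, and the forward model assumes each measured
signal is a linear combination of channel responses:

$$ B = W C + E, $$

with $B$ the signals × trials activation matrix, $C$ the k × trials channel
design, and $W$ the signals × k encoding weights. `iemr` estimates $W$ per
signal by ordinary least squares (`iem()`), and *inverts* the fitted model
on held-out data by the least-squares channel estimate

$$ \hat{C} = (W^\top W)^{-1} W^\top B_\text{test}, $$

(`predict.iem()`), giving each test trial a reconstructed *channel response
profile* in arbitrary units.

Plain OLS is not incidental: because both stages are exact linear
least-squares solves, replacing the basis $b$ by $T b$ for any invertible
$k \times k$ matrix $T$ changes the weights to $W T^{-1}$, leaves the
training residuals identical, and maps the reconstructions to
$T \hat{C}$ — so any between-condition difference expressed in one basis is
recoverable losslessly from another via $T^{-1}$. Ridge or any untransformed
penalty would break this exact equivariance, which is the package's central,
tested property. Rank problems are handled by tolerance-guarded checks
(relative smallest singular value, default $10^{-8}$) with typed errors
rather than silent regularization.

## Channel bases

`cosine_basis(k, exponent)` builds the standard raised-cosine set: channel
$i$ centered at $180 i / k$ with sensitivity
$\max(0, \cos(\pi d / 180))^p$, $d$ the circular distance to the center.
Channels are unit-normalized (value 1 at their own center), which keeps
reconstructed profiles comparable across studies.

The exponent default deserves a note, because two desirable exact
properties pull in opposite directions:

* **Flat tiling.** An *even* power of the cosine is a trigonometric
  polynomial band-limited to harmonic $p$, so for even $p < 2k$ the sum of
  all channels is *exactly* constant over the feature axis. Odd powers —
  including the common $p = k - 1$ convention — are rectified and carry an
  infinite harmonic tail; their coverage ripples at about $3 \times 10^{-5}$
  for $k = 8$, $p = 7$.
* **Design rank.** When the experiment uses exactly the `k` channel centers
  as stimuli (as the built-in simulation does), the k × k design is
  circulant and its eigenvalues are the DFT of the channel shape sampled at
  the centers. An even power below $k$ lacks the lattice's Nyquist
  harmonic, so the design drops to rank $k - 1$ and the forward model is
  unidentifiable.

Both hold simultaneously iff $p$ is even and $k \le p < 2k$; the default is
the smallest such value, the largest even integer $\le k$ ($p = 8$ for the
standard 8-channel set, giving the exact coverage constant
$8\binom{8}{4}/2^8 = 2.1875$). The exponent remains a visible parameter for
users who want the historical odd-power shapes.

`delta_basis(k)` provides the orthogonal "stick" alternative: one-hot
channels that impose no smoothness, evaluated in closed form (a channel
responds 1 only when the stimulus coincides with its center), so stimuli at
the `k` centers yield an exact identity-patterned design. Any smoothness
seen in profiles reconstructed under a delta basis is then a property of
the data, not the model.

`bimodal_transform(k, alpha)` supplies the concrete invertible mixing
matrix $T = I + \alpha S$, with $S$ the circular shift-by-$k/2$
permutation: each transformed channel acquires a second mode half a period
away with relative height $\alpha$. Its eigenvalues are $1 \pm \alpha$ for
even $k$, so any $0 < \alpha < 1$ is safely invertible ($\alpha = 1$ is
singular, and is rejected). $\alpha = 0.5$ is the package's reference
value. `apply_transform()` composes arbitrary invertible transforms and
records the cumulative lineage so `unmix_profiles()` can always map
reconstructions back to the canonical basis.

## The simulator

`simulate_dataset()` emulates the generative story behind attention-style
gain experiments: each of `n_voxels` (default 100) voxels sums the
responses of its own `n_neurons` (default 100) neurons; a neuron has a
circular-Gaussian tuning curve with uniformly drawn preferred feature
(0–180°), bandwidth $\sigma$ (default 10–40°) and amplitude (default
0.5–1.5 response units). Per trial, i.i.d. Gaussian noise (SD `noise_sd`)
is added to every neuron's response **before** the condition's
multiplicative gain is applied (defaults: gain 1.0 for condition 1, 1.8 for
condition 2) — so the gain scales signal and noise together, and the
noiseless dataset is *exactly* linear in the gain. Trials cover 8
orientations × 2 conditions × 8 repeats, split into balanced train/test
halves within every cell. The reference noise level for the noisy regime is
`noise_sd = 10`, an SNR regime where per-neuron noise dwarfs per-neuron
signal and recovery relies on pooling across 100 neurons, 100 voxels and
repeated trials; bandwidth and amplitude ranges are the package's choice of
a plausible heterogeneous population, are exposed in `sim_config()`, and
are recorded in the dataset's ground truth.

What the simulator deliberately omits: hemodynamics, temporal
autocorrelation, voxel-level (post-summation) noise, correlated noise
across voxels, and any non-multiplicative condition effect. Passing tests
therefore demonstrate the *algebra* of the analysis and the estimator's
behavior under idealized neural noise — not robustness to realistic fMRI
noise structure.

## Quantification

Recentering (`recenter_profiles()`) circularly shifts each trial's profile
so the channel tuned to the true stimulus lands at slot
$\lfloor k/2 \rfloor + 1$; it requires stimulus values to coincide with
channel centers (true in the simulation; sub-channel interpolation is out
of scope) and refuses transformed bases, whose channels have no single
preferred feature — those are first mapped back via the lineage inverse.
Ties in any argmax reporting go to the lowest channel index.

The between-condition measure is the model-free AUC ratio
(`auc_gain_ratio()`): the circular trapezoid area under the
condition-averaged profile, which for evenly spaced centers is
$(180/k) \sum_j \hat{c}_j$, taken for condition 2 over condition 1.
Averaging precedes the ratio (noise-robust denominator); because the area
is invariant to circular shifts, transformed-basis profiles are quantified
directly without recentering. A two-parameter amplitude + baseline fit
against the canonical channel shape (`fit_amplitude_baseline()`) is
provided for unimodal profiles.

`gain_recovery_experiment()` is the Monte-Carlo harness: repeat $r$ uses
seed `base + r`, simulates, fits the fixed model on the train half, inverts
the test half and records the measured gain per basis variant. Noiselessly
the measured gain equals the modeled gain to floating-point precision, for
every invertible basis, because the whole pipeline is linear. With neural
noise the AUC ratio is a ratio estimator and carries a small positive
$O(\text{Var}/\mu^2)$ bias (well under 1% at the reference noise level),
visible only relative to the Monte-Carlo standard error at large repeat
counts.

## Numerical and design choices

* Tolerances: algebraic identities are asserted at $10^{-8}$ (max-abs or
  relative as appropriate); invertibility and rank guards use relative
  smallest singular value $> 10^{-8}$.
* The fixed-model training scheme uses the simulator's balanced train half
  (equal trials per orientation × condition), so one weight matrix
  reconstructs both conditions on equal footing; `kfold` (including
  leave-one-trial-out) is available for within-dataset schemes, with fold
  assignment balanced across cells and a leakage check on explicit
  partitions.
* Problem sizes in the shipped tests: the full 100 × 100 reference
  simulation for the end-to-end checks (the noisy gain-recovery suite uses
  100 repeats), and reduced populations (≈ 12 voxels × 15 neurons) for
  algebraic unit tests, where size is irrelevant to the property under
  test.
* All randomness flows through `sim_config(seed = ...)`; a dataset is a
  pure function of its config.

## Limitations

Channel response profiles are reported in arbitrary units and should be
compared only under a fixed encoding model; the package refuses the
operations (recentering transformed bases, overlapping train/test
partitions) that would silently break that comparability. Nothing here
licenses inference about single-neuron tuning from channel profiles: the
reconstruction lives in the modeled channel space, and different bases
related by invertible transforms describe the same data equally well.
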