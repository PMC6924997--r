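# iemr — inverted encoding models for population-level neural data

`iemr` implements the inverted encoding model (IEM) technique used in
computational neuroimaging to study feature representations (e.g. visual
orientation) in multivariate signals such as fMRI voxel patterns, together
with a ground-truth neuron-population simulator for validating the analysis
end to end.

The forward model treats each measured signal as a linear combination of
`k` hypothesized feature channels. With `B` the signals × trials activation
matrix and `C(θ)` the channel responses predicted for each trial's stimulus,

```
B = W C + E          (training: W estimated per signal by OLS)
Ĉ = (WᵀW)⁻¹ Wᵀ B*    (inversion: channel response profiles for new data B*)
```

Reconstructed channel response profiles `Ĉ` are in arbitrary units and are
compared between experimental conditions under a *fixed* encoding model.
Because both stages are exact least squares, replacing the basis `b` by
`T·b` for any invertible `T` leaves the fit quality unchanged and maps the
profiles to `T·Ĉ` — so between-condition differences (e.g. a multiplicative
gain) are preserved across invertible linear transforms of the basis, and a
"bimodal" variant of the basis can always be mapped back to the unimodal
one via `T⁻¹`. The package demonstrates and tests this property explicitly,
and quantifies condition differences with a model-free AUC gain ratio that
is valid under any basis shape.

For whom: researchers analyzing orientation/feature reconstructions from
fMRI (or similar multichannel) data who want a small, fully tested,
ground-truth-validated reference implementation of basis construction,
fitting, inversion, recentering and gain quantification.

## Worked example

Simulate a noiseless dataset of 100 voxels (each the sum of 100
circular-Gaussian-tuned neurons) over 8 orientations × 2 conditions, where
condition 2 carries a multiplicative neural gain of 1.8; fit the forward
model on the balanced training half, invert it on the held-out half,
recenter each trial's profile on its true orientation, and compare
conditions:

```r
library(iemr)

cfg <- sim_config(gains = c(1, 1.8), noise_sd = 0, seed = 42)
ds  <- simulate_dataset(cfg)
rec <- reconstruct(ds, cosine_basis(8), scheme = "fixed")
avg <- condition_average(recenter_profiles(rec))
round(avg, 3)
#>           condition1 condition2
#> offset-90      0.000      0.000
#> offset-68      0.000      0.001
#> offset-45      0.045      0.080
#> offset-22      0.379      0.682
#> offset+00      0.714      1.286
#> offset+22      0.379      0.682
#> offset+45      0.045      0.080
#> offset+68      0.000      0.001

auc_gain_ratio(avg[, 2], avg[, 1], basis_kind = "cosine", modeled_gain = 1.8)
#> AUC gain ratio (condition 2 / condition 1): 1.8  [modeled gain 1.8]  (cosine basis)
```

Both condition profiles peak at the trial's true orientation
(`offset+00`), and the ratio of the areas under the two profiles recovers
the simulated gain exactly: with zero noise the whole pipeline is linear in
the underlying neural response.

The full demonstration — both the raised-cosine basis and its bimodal
(invertibly transformed) counterpart, the lossless inverse-transform round
trip, and gain recovery with neural noise (SD 10, 20 repeats) — runs as:

```r
reproduce_fig1(seed = 42, n_repeats = 20)
#> Invertible-transform demonstration report
#>   modeled gain (condition 2 / 1): 1.8
#>   noiseless measured gain: cosine 1.8, bimodal 1.8
#>   transform equivariance max-abs error: 1.12e-13
#>   round-trip (inverse transform) max-abs error: 8.12e-14
#>   noisy gain recovery:
#>          basis_kind modeled_gain measured_gain_mean dispersion n_repeats seed
#> cosine       cosine          1.8           1.766812  0.1419453        20   42
#> bimodal transformed          1.8           1.766812  0.1419453        20   42
#>   overall: PASS
```

The cosine and bimodal rows agree exactly here because the reference
bimodal transform has constant row sums, which the channel-sum AUC cannot
distinguish; the per-profile equivariance `Ĉ_bimodal = T·Ĉ_cosine` is
checked directly.

A command-line front end with `simulate`, `basis`, `reconstruct`,
`quantify` and `reproduce-fig1` subcommands is installed at
`system.file("cli", "iem_workbench.R", package = "iemr")`.

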