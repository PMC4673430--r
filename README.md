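# burstnet

Analysis of spontaneous multi-unit activity (MUA) on multielectrode
arrays (MEAs): network-burst detection against a rate-preserving
permutation null, per-channel burst-predictor scoring, neuronal-avalanche
statistics with bounded discrete power-law maximum likelihood, critical
branching-parameter estimation, and matched pre/post-insult comparison.
A probabilistic branching network model doubles as the package's
synthetic-data engine, so the entire chain runs, and is tested, without
any recordings.

The package is written for electrophysiologists and computational
neuroscientists working with dissociated-culture MEA data — in
particular for studying which electrodes *predict* network bursts and
how burst predictors fare under perturbations such as an excitotoxic
insult.

## What it computes

**MUA raster.** Voltage traces (channels x ms, 1 kHz) are high-pass
filtered (2nd-order Butterworth, 200 Hz) and thresholded per channel at
θᵢ = −k·median(|xᵢ|)/0.6745 (k = 5), giving a binary channels x ms
matrix. Channels with < 2 events or rates > 5 SD above the mean are
removed.

**Network bursts.** On the 10 ms presence raster, the population count
s(t) is compared with 100 surrogates in which each channel's firing
times are permuted while its rate is preserved. Bins where s(t) exceeds
the pooled 95th percentile of the surrogate counts are supra-threshold;
maximal runs of them are bursts. Cultures with < 5 bursts are excluded.

**Burst-prediction (BP) score.** For channel i,

    BP_i = (#bursts preceded by channel i within 50 ms / #bursts) / rate_i [Hz]

so a score separates *specific* pre-burst firing from tonic activity;
scores > 20 flag strong predictors.

**Avalanches and criticality.** Avalanches are maximal runs of non-empty
bins. Their sizes follow P(k) ∝ k^(−α) on [x_min, x_max] (observed
bounds), fitted by maximizing

    ℓ(α) = −α Σ ln xᵢ − n ln[ζ(α, x_min) − ζ(α, x_max + 1)]

with the Hurwitz-zeta normalizer. The branching parameter
σ = Σ_d d·p(d) is estimated from ancestor/descendant electrode counts in
the first two bins of each avalanche, with d = round(n_d/n_a),
ancestor-weighted p(d), and a refractoriness correction
n_max/(n_max − n_a); σ = 1 marks the critical point.

**Branching model.** N = 100 binary all-to-all units whose incoming
propagation probabilities sum to σ per unit; noisy-OR activation,
1-step refractoriness, and a single random unit seeded on silence. At
σ = 1 it produces avalanche-size slopes α ≈ 1.5, at σ = 1.2 flatter
(α ≈ 1.3), at σ = 0.8 steeper (α ≈ 1.7).

**Insult comparison.** Per-channel Δrate = rate_post − rate_pre, top-5
"high BP" vs "low BP" group contrasts, emergent predictors (pre score 0,
post > 0), PCA of score stability across sessions, and
correlation/Wilcoxon association reports.

## Worked example

Simulate a critical branching network, extract avalanches, and fit the
size distribution:

```r
library(burstnet)

net <- build_network(n_units = 100, sigma = 1.0, seed = 42)
r   <- simulate_network(net, steps = 100000, seed = 43)
r
#> <sim_raster> 100 units x 100000 steps (sigma = 1), 234123 events

fit <- fit_bounded_power_law(extract_avalanches(r)$n_events)
fit
#> <power_law_fit> alpha = 1.4762 on [1, 613], n = 16386, logLik = -48150.18

estimate_branching_parameter(r)
#> <branching_estimate> sigma = 1.0037 from 16386 pairs (n_max = 100, correction on)
```

The fitted slope sits at the 3/2 signature of a critical branching
process, and the estimator recovers σ ≈ 1 from the raster alone.

Score burst predictors on a synthetic session with three planted
predictor units (ids 20, 14, 5 here):

```r
ses <- simulate_planted_session(build_network(60, 1.0, seed = 1),
                                duration_ms = 120000, seed = 2)
z  <- bin_raster(ses$raster, B = 10)
b  <- detect_network_bursts(z, n_permutations = 100, percentile = 95, seed = 3)
bp <- compute_bp_scores(z, b, window_ms = 50)
cols <- c("channel", "pre_burst_hit_count", "n_bursts", "mean_rate_hz", "bp_score")
head(bp[order(-bp$bp_score), cols], 5)
#>  channel pre_burst_hit_count n_bursts mean_rate_hz   bp_score
#>       20                   3      387   0.05000000 0.15503876
#>        5                   3      387   0.05833333 0.13289037
#>       14                   4      387   0.09166667 0.11275546
#>       54                  16      387   0.49166667 0.08408882
#>        1                  14      387   0.50000000 0.07235142
```

The three planted units occupy the top three ranks: they fire rarely
(≈ 0.05–0.09 Hz vs 0.5 Hz background) but specifically before network
bursts, which is exactly what the rate-normalized score rewards. (Most
of the 387 detected "bursts" on this short, stationary-background
session are small population coincidences — the permutation detector
flags ≈ 5% of bins on stationary data by construction — which dilutes
hit fractions but not the ranking.)

`run_pipeline(run_config(mode = "simulate", sigma = 1.0, seed = 7))`
runs the whole chain (QC → bursts → BP → avalanches → fits → σ) and
writes every artifact plus a single `report.json`.

## Package layout

- `R/` — raster I/O and preprocessing, burst detection and BP scoring,
  avalanche/power-law/branching estimation, the branching simulator and
  fixture generators, insult comparison, pipeline orchestration.
- `tests/testthat/` — unit, property and end-to-end acceptance tests
  (all fixtures are generated in code).
- `vignettes/burstnet-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical details, limitations.
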