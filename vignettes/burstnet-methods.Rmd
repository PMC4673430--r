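---
title: "Methods: network bursts, burst predictors, and avalanche criticality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network bursts, burst predictors, and avalanche criticality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`burstnet` analyzes spontaneous multi-unit activity (MUA) recorded from
dissociated cortical cultures on multielectrode arrays (MEAs), and ships a
branching network model that generates synthetic rasters with the same
statistical signatures, so the full analysis chain can be exercised,
calibrated and tested without recordings. This vignette explains each
stage's model and assumptions, the tunable parameters and their defaults,
the numerical choices, and what the synthetic fixtures do and do not
establish about real data.

```{r setup}
library(burstnet)
```

## From voltage to the binary MUA raster

A recording is a channels-by-time matrix of extracellular voltage in
microvolts at 1 kHz (recordings acquired faster are decimated first, e.g.
by 5 from a 5 kHz acquisition; `downsample_recording()`). MUA is isolated
with a 2nd-order high-pass Butterworth filter at 200 Hz
(`highpass_filter()`), applied causally by default to match online
acquisition; a zero-phase forward-backward mode is available when phase
distortion matters more than causality.

Detection (`detect_mua()`) marks a 1 at every millisecond where the
filtered voltage is at or below a per-channel negative threshold
$\theta_i = -k\,\hat\sigma_i$. The noise scale $\hat\sigma_i$ is, by
default, the robust estimate $\mathrm{median}(|x_i|)/0.6745$ — the
standard convention in extracellular spike detection, chosen because the
plain standard deviation is inflated by the spikes themselves; `noise =
"sd"` switches to the plain SD. The multiplier defaults to $k = 5$.
Detection is one-sided (negative deflections only), and a 2 ms dead time
suppresses secondary crossings of a single waveform; 0 disables it. These
conventions (robust scale, $k = 5$, short dead time) are the ones a
practitioner would consider standard; all are exposed as arguments.

Channel QC (`qc_channels()`) removes channels with fewer than two events
and channels whose rate exceeds the across-channel mean by more than five
standard deviations. Both rules are evaluated against the single
pre-removal rate distribution and applied once: QC is defined relative to
the original recording, and re-applying it to its own output is
deliberately not supported as a convergent procedure. Note that with $n$
channels a lone outlier can be at most $(n-1)/\sqrt{n}$ sample SDs from
the full-sample mean, so the 5 SD rule can only ever fire with roughly 27
or more channels — appropriate for 59-electrode arrays, and worth knowing
when applying the rule to small simulated rasters.

Session duration is always taken from the data; the package never assumes
a fixed recording length.

## Network bursts against a rate-preserving permutation null

Burst detection (`detect_network_bursts()`) operates on the 10 ms presence
raster (`bin_raster()`, entry 1 iff the channel has at least one event in
the bin). The population count per bin is compared against surrogates in
which each channel's presence bins are independently permuted in time:
every channel's firing rate is preserved exactly, while all temporal
structure — within channels and across them — is destroyed. One hundred
permutations are used by default.

The threshold is the 95th percentile of the surrogate population counts,
pooled across bins and permutations, giving a single flat threshold. The
pooled choice reflects that the surrogate counts are stationary by
construction, so per-bin percentiles would only add noise; a per-bin mode
(`pooled = FALSE`) is provided for comparison. Exceedance is strict
(`>`), and maximal runs of consecutive supra-threshold bins form one
burst each, with no merge gap. On a stationary raster with no burst
structure this procedure flags close to (and by design at most about) 5%
of bins — the detector is a calibrated test, not a clustering heuristic,
and the test suite checks this null calibration directly.

Cultures with fewer than five detected bursts in a baseline session carry
too little information for predictor scoring and are excluded
(`qc_culture()`).

## Burst-prediction scores

For each channel, `compute_bp_scores()` counts the bursts preceded by at
least one of the channel's presence bins within 50 ms strictly before the
onset bin — the onset bin itself is excluded, since prediction must
precede the burst — and divides the hit fraction by the channel's mean
rate in Hz:

$$\mathrm{BP}_i = \frac{\#\{\text{bursts preceded by channel } i\} / \#\text{bursts}}{\bar r_i}.$$

The rate normalization separates *specific* pre-burst firing from mere
tonic activity: a channel that fires everywhere also fires before bursts,
but its high rate divides its score back down. Channels with zero rate
score 0 (rather than NaN) so tables stay total. Scores above 20 flag
"strong" predictors; this cutoff is applied as given in the literature
this pipeline follows and is an argument, not a constant. Hits within a
preceding burst's interval still count, and the window is 50 ms (5 bins)
by default — both configurable.

In a 20-minute session, a perfectly specific predictor that fires once
before each of $n_B$ bursts and nowhere else scores
$1200\,\mathrm{s}/n_B$; scores above 20 therefore correspond to specific
predictors of relatively rare bursts, which is the regime the cutoff is
meant for. On short synthetic sessions with frequent planted events the
same mechanics produce proportionally smaller absolute scores, which is
why the fixture-based tests compare planted scores against the
within-session score distribution rather than against the absolute
cutoff.

## Avalanches and the bounded discrete power-law MLE

An avalanche (`extract_avalanches()`) is a maximal run of consecutive
non-empty bins, delimited by empty bins, summarized by duration, number
of distinct active units, and total event count. For experimental-style
1 kHz rasters the default delimitation bin is 1 ms (durations are then in
ms); for simulator output one model step is one bin. The avalanche bin
width on experimental data is a genuinely open choice — common practice
ranges from the mean inter-event interval to a fixed small bin — and the
package exposes it rather than hard-coding it.

Sizes and durations are fitted with a bounded discrete power law
$P(k) \propto k^{-\alpha}$ on $[x_\min, x_\max]$, with the bounds set to
the observed minimum and maximum. The log-likelihood is

$$\ell(\alpha) = -\alpha \sum_i \ln x_i - n \ln Z(\alpha),\qquad
Z(\alpha) = \sum_{k=x_\min}^{x_\max} k^{-\alpha}
= \zeta(\alpha, x_\min) - \zeta(\alpha, x_\max + 1),$$

where $\zeta(\cdot,\cdot)$ is the Hurwitz zeta function. `bounded_zeta()`
evaluates $Z$ by direct summation for supports up to $10^5$ terms and by
an Euler–Maclaurin tail expansion beyond that; the integral term of the
expansion is computed through `expm1` so the formula is stable through
$\alpha = 1$, and the two branches agree to better than $10^{-9}$
relative error where both run, which the tests assert. The maximization
(`fit_bounded_power_law()`) is 1-D `optimize()` over
$\alpha \in [0.5, 5]$ with tolerance $10^{-4}$; an estimate within
numerical reach of the interval edge is flagged (`at_boundary`) and
warned about instead of being silently returned. The optimizer is
cross-checked in the tests against an independent 0.001-step grid search
of the same likelihood, and against samples drawn by the exact
inverse-CDF sampler (`sample_bounded_power_law()`); parameter recovery at
$n = 10^4$ is within 0.05 of the generating exponent in at least 95% of
seeded replicates.

Estimating $x_\min$/$x_\max$ from data (rather than taking the observed
extremes), and goodness-of-fit comparisons against alternatives such as
the lognormal, are out of scope by design.

## Branching parameter

`estimate_branching_parameter()` quantifies propagation as the expected
number of descendant electrodes per ancestor electrode. For each
avalanche, the first two bins give one observation: $n_a$ ancestors, then
$n_d$ active electrodes, with $d = \mathrm{round}(n_d/n_a)$, rounded half
away from zero (so $d = 1.5 \mapsto 2$; plain `round()` in R rounds half
to even, which would bias ties). Avalanches of a single bin contribute
$d = 0$ terminations. The distribution $p(d)$ is ancestor-weighted —
$p(d) = \sum_{e: d_e = d} n_a^{(e)} / \sum_e n_a^{(e)}$ — and
$\hat\sigma = \sum_d d\, p(d)$.

Because an electrode active in the first bin is refractory in the second,
the number of electrodes available to register descendants is reduced by
$n_a$; with `correction = TRUE` (default) each observation's weight is
multiplied by $n_\max/(n_\max - n_a)$ to compensate, where $n_\max$ is
the number of electrodes. Observations with $n_a = n_\max$ have no
available electrodes and are skipped with a warning. The estimator
reports both corrected and uncorrected values through the pipeline. Only
the first bin pair of each avalanche is used by default (an all-pairs
mode exists), matching the ancestor/descendant construction the
correction is derived for.

## The branching network model

`build_network()` draws an all-to-all network of $N$ binary units
(default $N = 100$): each unit's incoming propagation probabilities are
uniform draws rescaled so the presynaptic sum equals $\sigma$ exactly.
Entries pushed above 1 by the rescaling (possible at large $\sigma$) are
clipped with the excess redistributed proportionally to the remaining
headroom, which restores the column sum in one pass.

`simulate_network()` runs noisy-OR dynamics: unit $j$ fires at $t+1$ with
probability $1 - \prod_{i \in A_t}(1 - p_{ij})$ over the active set
$A_t$. The noisy-OR (independent synapses) is the standard choice
consistent with $\sigma$ being the expected descendant count of a lone
ancestor. Two deliberate model choices:

* **Refractoriness.** A unit active at $t$ cannot fire at $t+1$. Without
  this, a supercritical network ($\sigma > 1$) settles into a saturated
  steady state of continuous activity instead of discrete large bursts,
  which contradicts both the bursty appearance of supercritical rasters
  and the premise of the branching estimator's refractoriness correction.
  With refractoriness, seeded runs of $10^5$ steps give avalanche-size
  slopes near 1.5 at $\sigma = 1$, near 1.3 at $\sigma = 1.2$, and near
  1.7 at $\sigma = 0.8$ — the expected ordering and values for this model
  class. The toggle (`refractory = FALSE`) exists so the estimator's
  correction can be exercised against a memoryless model as well.
* **Drive.** On total silence, one uniformly chosen unit is activated at
  the next step (`seed_on_silence`), so avalanches are cleanly delimited
  by single silent steps and every avalanche has a well-defined single
  seed. A weak Poisson drive is available for ongoing-background
  experiments, at the cost of occasionally merging avalanches.

At $\sigma = 0.5$ the mean avalanche size matches the subcritical
branching closed form $1/(1-\sigma) = 2$ within sampling error (the
$-\sigma/N$ self-connection and collision corrections are below the test
tolerance at $N = 100$).

## Synthetic sessions, planted predictors, and insult fixtures

`simulate_planted_session()` composes an MEA-like session: independent
background spiking at 0.5 Hz per channel; network bursts scheduled as a
Poisson process at 0.05 Hz with a 2 s minimum separation, each realized
by seeding 10% of the units of a $\sigma = 1$ network and running the
cascade until extinction (cascades are redrawn, up to 20 attempts, until
they recruit at least half the units, so every scheduled event is a
genuine network-wide burst); and a few planted predictor units that are
silent except for one event placed 10–50 ms before each burst onset with
probability 0.9 plus 0.02 Hz of unspecific background. These settings
emulate the regime reported for cortical cultures — strong predictors are
rare, fire at under 0.5 Hz, and precede most bursts — and the default
session length is a full 20-minute recording. Tests and the acceptance
script use 1–2 minute sessions and 30–60 units where the checks are
relative (planted versus non-planted score percentiles), which these
sizes already decide clearly.

`generate_session_pair()` makes a matched baseline/post-insult pair from
the same network and planted identities, then perturbs the post session:
a profile-dependent fraction of the non-predictor units is silenced
outright (0 / 20% / 50% for control / low kill / high kill), the
survivors' event trains are thinned (retention 1 / 0.9 / 0.6) with
log-normal rate jitter (s.d. 0.05), and the planted predictors are left
untouched. The ground truth (planted ids, silenced ids, realized per-unit
rate changes) is returned alongside. The kill fractions are chosen to
bracket the published viability range for 10–20 minute excitotoxic
exposures; they parameterize the fixture, not a biological claim.

What these fixtures establish: that the detection–scoring–comparison
chain recovers planted structure through every stage (planted predictors
top the BP ranking; their $|\Delta\text{rate}|$ median sits below the
weak units' median in high-kill pairs; silenced channels appear as
inactive with $\Delta\text{rate} = -r_\text{pre}$). What they do not
establish: anything about real tissue — the background is Poisson rather
than weakly correlated, bursts are stereotyped cascades of one network,
electrode geometry and slow developmental drift are absent, and predictor
"strength" is planted rather than emergent. Passing tests validate the
computations, not the biology.

## Pre/post comparison

`delta_rate()` reports $r_\text{post} - r_\text{pre}$ per channel
(negative = post-insult decrease), optionally alongside min–max
normalized rates for plotting conventions that scale each session to
$[0,1]$; the raw Hz difference is always kept. Channels dead after the
insult are retained with rate 0 and flagged, not dropped, so
inactive-electrode percentages remain computable.

`compare_high_low_bp()` ranks channels by baseline score and splits top
$k = 5$ ("high BP") versus the rest. Ties across the boundary are broken
deterministically — score descending, then baseline rate ascending (the
more specific predictor wins), then channel id — and reported. For one
culture the default test is a two-sample $t$ on post-insult scores
between groups; for several cultures, a paired $t$ across cultures on the
per-culture group means. Both orientations are surfaced because the
published df conventions for this contrast are ambiguous; a fully
degenerate contrast (zero variance) is flagged with no $p$ value rather
than reported as significant.

`bp_stability_pca()` is a plain eigendecomposition of the session
covariance of a channels-by-sessions score matrix (centered, unscaled),
reporting variance fractions and the correlation of PC1 channel scores
with per-channel mean score; PC1's sign is fixed to make that correlation
non-negative. `association_report()` wraps the Pearson correlations (BP
vs rate across channels; % inactive electrodes vs mean BP across
cultures) with their exact $n-2$ df, and a paired Wilcoxon signed-rank
comparison of pre vs post score distributions using the normal
approximation so a $z$ value can be reported.

## Orchestration and determinism

`run_pipeline()` executes the whole chain from a flat `key = value`
config (`run_config()`, `read_run_config()`), writing every intermediate
artifact and a single JSON report. Every stochastic stage derives its
seed from the master seed by fixed offsets (+1 network, +2 simulation,
+3 permutations), so identical configs produce identical reports — the
test suite asserts byte-level equality of two runs. Stage failures abort
with the stage name; a culture failing the five-burst rule is an
exclusion recorded in the report, not an error.

## Problem sizes and limitations

The simulation-based checks in the test suite and the acceptance script
use $N = 100$ units and $10^5$ steps for slope and $\sigma$ recovery,
$10^4$–$10^5$ samples for MLE recovery, and 1–2 minute planted sessions
of 30–60 units for detector and scoring checks; these sizes make each
check decisive (tolerances are set by the statistics above, not by the
sizes) while keeping a full run in the minutes range on one core.

Known limitations: the power-law machinery fits within fixed observed
bounds and does not test against alternative heavy-tailed families; the
branching estimator uses only avalanche-initial bin pairs by default and
assumes a homogeneous electrode pool in its refractoriness correction;
the model has no spatial structure, inhibition, or plasticity; and BP
score magnitudes depend on burst frequency and session length, so they
are comparable within a session design but not across different ones
without renormalization.
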