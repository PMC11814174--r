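---
title: "Methods: population decoding and category separation in IT spike data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population decoding and category separation in IT spike data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsep)
```

## The problem

Neurons in macaque inferior temporal cortex respond selectively to complex
visual objects, and the two IT subdivisions — posterior TEO and anterior
TE — are both sufficient to support object categorization. A central
question is whether they process category information differently: does the
category signal carried by a population stay constant over the course of a
stimulus presentation (a feed-forward, "read-once" code), or does it build
up within a trial and strengthen with category learning (suggesting
recurrent or top-down contributions)?

`popsep` implements the analysis chain used to ask this question with
chronically recorded spike data from passive-fixation sessions: per-neuron
visual-responsiveness classification, trial-averaged population vectors
over sliding time windows, cross-validated logistic-regression decoding of
the binary cat/dog category, and Fisher-discriminant quantification of
category separation as a Mahalanobis distance. Because such recordings are
rarely shareable, the package also ships a generative model of the
recordings whose parameters are recoverable by the chain, so that every
stage is testable end-to-end.

## Conventions

All times are milliseconds relative to stimulus onset (`0` = onset) and all
windows are half-open intervals `[start, end)`, so tiling windows never
double-count a spike. Rates are spikes/s. A dataset (`spike_dataset`)
stores spikes per presentation in long format, with the stimulus catalogue
(image id, category) and session metadata (area, session, monkey). The
default analysis epoch is `[-300, 400)` ms, covering the 200–300 ms
enforced pre-onset fixation and a full 350–400 ms presentation; synthetic
datasets used for late-window contrasts extend it to `[-300, 450)` so that
100-ms windows starting as late as 350 ms stay inside the epoch.

## Visual responsiveness

A neuron×image test compares, trial by trial, the firing rate in a
baseline window with the rate in a stimulus window (two-sided paired t on
the per-trial rate differences). Working on rates rather than counts makes
unequal window widths comparable; with equal widths the p-value is
identical. Defaults: baseline `[-200, 0)` (inside the enforced fixation),
stimulus `[0, 350)` (the minimum presentation). When every per-trial
difference is exactly zero the test cannot reject and returns p = 1.

The per-image p-values are corrected with the Benjamini–Hochberg step-up
rule. The correction family is the set of image tests *within one neuron*
(`family = "per_neuron"`, 520 tests at full scale): this keeps each
neuron's classification self-contained and independent of which other
neurons happen to be in the session. A `family = "global"` switch pools
all neuron×image tests instead. Neurons are then classified `only_dog` /
`only_cat` / `both` / `none` by which categories contain at least one
significant image; anything but `none` counts as visually responsive, and
pooled percentages are `100 * sum(total - none) / sum(total)`.

Firing-rate functions are trial-pooled Gaussian kernel density estimates
(bandwidth 10 ms) scaled to spikes/s, so the time integral equals the mean
spike count per trial.

**Onset latency** is not given by a standard rule, so the package defines
one and reports it with every estimate: *detection* requires the rate to
exceed baseline mean + 3 baseline SDs continuously for at least 20 ms
(otherwise the latency is undefined); the *reported* latency is the first
post-onset time the rate reaches halfway between the baseline mean and the
post-onset maximum. The mid-height rule is used for localisation because a
Gaussian-smoothed step crosses a low threshold roughly 1.5 bandwidths
*before* the true onset (the bias grows with response height), whereas the
mid-height crossing of a smoothed step sits exactly at the step. On strong
synthetic step responders the rule recovers the true onset to within a few
milliseconds, with a small (+2–3 ms) late bias from peak overshoot.

## Population vectors and decoding

For a window `[t, t+Δt)` the population vector of image *i* is the
N-vector of trial-averaged firing rates (count summed over the image's
trials, divided by trial count and Δt). Populations recorded in separate
sessions or animals are pooled as a *pseudo-population* by concatenating
their per-image columns — valid because rows are indexed by shared image
identity, and the only construction available for non-simultaneous
recordings. Provenance (contributing dataset ids) is recorded on every
pooled set. Within-monkey trial averaging happens before concatenation, so
unequal trial counts across animals do not weight the pooled vector.

The decoder is binary logistic regression, `y(Φ) = σ(wᵀΦ)`, fitted by
minimising the cross-entropy error with an optional ridge penalty
(intercept included and unpenalised), via Newton–Raphson with step
halving. The default penalty `lambda = 1` is deliberately weak: with
feature counts approaching the number of training rows, individual windows
can be linearly separable and the unpenalised optimum diverges; a weak
ridge keeps the fit finite without materially changing decisions.
`lambda = 0` recovers the plain maximum-likelihood model (and matches
`glm` to five decimals in the tests). Hard decisions use σ ≥ 0.5, with
the measure-zero tie decided as "dog".

Accuracy is evaluated by stratified k-fold cross-validation (default
k = 10): per class, image rows are shuffled once with a seeded RNG and
dealt round-robin into folds. The *same* fold assignment is reused for
every sliding window, so accuracy curves differ only through window
content and can be compared pointwise — which the paired tests on curves
require. The default window grid is 100-ms windows slid in 1-ms steps
(100 ms resolves within-trial dynamics without smoothing them away);
tests and demonstrations use coarser slides (5–50 ms) purely for runtime.

## Category separation

With class means `m1` (cat) and `m2` (dog), within-class scatter
`S_W = Σ_k Σ_{n∈C_k} (x_n − m_k)(x_n − m_k)ᵀ` and between-class scatter
`S_B = (m2 − m1)(m2 − m1)ᵀ`, Fisher's criterion
`J(w) = wᵀS_B w / wᵀS_W w` is maximised by the top eigenvector of
`S_W⁻¹S_B`, which in the two-class case has the closed form
`ŵ ∝ S_W⁻¹(m2 − m1)`. The package normalises `ŵᵀS_W ŵ = 1`, reports the
dog-positive direction, and quantifies separation as the Mahalanobis
distance `D = sqrt((m2 − m1)ᵀ S_W⁻¹ (m2 − m1))`, with
`J(ŵ) = λ = D²` asserted to 1e-8 relative at construction. Note `S_W` is
a *scatter* (not covariance) matrix, so `D²` carries an implicit
`1/(n_images − 2)` relative to the covariance-metric distance; the
analytic oracle below uses the same convention.

Because N can approach the within-class degrees of freedom, `S_W` may be
near-singular. Three inversion policies are provided and recorded in every
output: `ridge` (default; Tikhonov term `1e-6·trace(S_W)/N` on the
diagonal), `strict` (plain solve, refusing condition numbers above 1e12),
and `pinv` (spectrum truncated at 1e-10 relative). Under `ridge` the
criterion is evaluated in the same stabilised metric that was inverted, so
the `J = D²` identity holds by construction; with exact inversion the
metrics coincide.

## The generative model

`generate_dataset()` draws inhomogeneous-Poisson spike trains with
per-neuron rate

λ(t) = max(0, b + 1[t ≥ L] · (g + s·c·p(t) + ε)),

where `b` is the baseline rate, `L` the response latency, `g` the
category-independent visual gain, `s ∈ {0, ±κ}` the signed category
contrast (zero for non-selective neurons; κ = `category_contrast ×
training_gain`), `c = ±1/2` the category code, `p(t)` the within-trial
contrast profile, and `ε ~ N(0, σ_ε²)` a per-(neuron, image) idiosyncratic
offset that makes images within a category similar but not identical —
without it the 520-image decoding problem would be trivially separable.
The `step` profile (contrast constant from the latency on) emulates the
temporally flat TEO-like representation; the `ramp` profile (contrast
growing linearly from the latency to `ramp_end`) emulates the TE-like
within-trial growth, and `training_gain > 1` models the post-training
strengthening of the TE category signal.

Spiking is Poisson without refractoriness: every analysis uses windowed
counts only, for which the Poisson assumption suffices and keeps the
separation oracle closed-form. Trains are generated by thinning
(homogeneous candidates at the per-(neuron, image) rate ceiling, accepted
with probability λ(t)/λmax), fully vectorised over trains, from one
private seeded RNG stream per call with a fixed generation order — the
same config and seed always reproduce the same spikes, and the caller's
RNG state is untouched.

Default parameters are anchored to the published population statistics of
the recordings the model emulates: 260 images per category; baseline rates
of a few spikes/s (mean 5 ± 2, matching session means of 1.3–5 spikes/s);
onset latencies of 60 ± 20 ms (session means 38–107 ms, grand means
61–72 ms); visual response gain 10 ± 5 spikes/s; per-image trial counts in
the 5–19 range (default 10); presentation durations drawn from 350–400 ms.
Where the recordings give no number the defaults are modelling choices,
stated once here: category contrast 5 spikes/s with half the neurons
selective (category-selective rate differences in IT are a fraction of the
visual response), idiosyncratic per-image scatter 2 spikes/s, ramp
saturation at 350 ms (the minimum presentation length), and
`training_gain = 1.5` for post-training TE demonstrations (the effect size
of training is not quantified anywhere; 1.5 is a clearly-visible but not
extreme strengthening, and is swept in tests). Rate truncation at zero is
applied after summing components; the analytic oracle ignores truncation,
so oracle-based tests keep baselines at least ~3 SDs above the modulation.

### The separation oracle

`expected_window_separation()` returns the large-trial expected D for a
window under a config, evaluated at the population-mean parameters (exact
when the between-neuron sds are zero). Per selective neuron the
dog-minus-cat mean-rate difference is `δ = κ·p̄` with `p̄` the profile mean
over the window, and the within-class variance of the trial-averaged rate
is Poisson counting noise plus idiosyncratic variance,
`σ² = λ̄/(n_trials·Δt) + (σ_ε·q)²` (`q` = fraction of the window past the
latency). With `f·N` selective neurons and n images,
`D = sqrt(f·N·δ²/σ² / (n − 2))`. Two finite-sample effects are *not* in
the oracle and set its accuracy limits: the Wishart bias of inverting an
estimated scatter (inflating D² by roughly `(n−2)/(n−2−N−1)`) and the
noise floor contributed by estimated class means (≈ `N·(1/n₁+1/n₂)` added
to the quadratic form). Recovery tests therefore use configurations where
both are small (10 neurons, 200 images, 200 trials/image), where empirical
D matches the oracle within a few percent.

## Statistical comparisons

Accuracy curves are compared with a paired t-test, paired by window start
(the only index two curves share); the pairing unit is recorded in every
report. Separation curves are compared with a Mann–Whitney U-test between
the D values of two disjoint window-start ranges (defaults `[0, 100]` vs
`[250, 350]` ms), exact for combined n ≤ 20 without ties and
normal-approximated with tie correction otherwise. Responsive-neuron
proportions are compared with a pooled two-proportion z-test. All
p-values are reported raw, with no multiplicity correction across
comparisons.

One caveat is inherent to the window-range comparison and documented
rather than hidden: with a 1-ms slide, consecutive 100-ms windows share
99% of their data, so the D "samples" entering the U-test are strongly
autocorrelated — a 101-sample range contains roughly two statistically
independent values. The test is therefore anticonservative under the null
of equal separation, and a flat category signal can still produce a
significant early-vs-late contrast through slow drift of the estimation
noise (and, for ranges overlapping the onset transition, through the
latency itself). The package replicates the procedure as defined by
default and offers `thin = k` to subsample every k-th window as a
robustness check. For establishing that a representation is genuinely
flat, the analytic oracle and direct ratio comparisons (e.g. the
late/early D ratio of a ramp vs a step population) are the more reliable
instruments, and that is how the package's own tests verify the
flat-vs-ramping area contrast.

## The pipeline

`run_config()` + `run_pipeline()` sequence the whole chain for a named set
of cells (area × session conditions, each a synthetic config or a dataset
directory): simulate/load → classify → decode → separate → compare →
report. One top-level seed expands deterministically into per-cell
simulation seeds and the fold-shuffling seed, so runs are reproducible end
to end and two runs with identical configs produce byte-identical
artifacts (stage timings go to a log file). Every result-affecting
configuration field is echoed into the run directory, and `report.json`
is a pure function of the written artifacts. A bundled four-cell
demonstration (`demo_config_path()`) reproduces the qualitative area
contrast at reduced scale: flat TEO cells, ramping TE cells, post-training
gain in TE only.

## Problem sizes in tests

The test suite and the acceptance script run at reduced scale, chosen as
this package's own trade-off between statistical resolution and runtime on
a single CPU: area contrasts use 50 neurons, 40 images/category and
10 trials/image over 20 seeded replicates; chance calibration uses an
81-window grid at a 5-ms slide; oracle recovery uses 10 neurons with
200 images and 200 trials/image; null error control uses 40 neurons with
the full 520-image catalogue at 19 trials/image. At these scales the
decoder saturates near perfect accuracy in late high-signal windows —
expected with ~50 informative features and 80 images, and no statement
about full-scale accuracy values.

## Known limitations

- Poisson spiking without refractoriness or cross-neuron noise
  correlations; windowed counts are faithful, spike-train fine structure
  is not. Correlated noise, which can limit real pseudo-population
  decoding gains, is absent by construction.
- The pseudo-population construction assumes category signals align
  across animals by image identity; real inter-animal heterogeneity is
  only partially emulated (per-dataset neuron draws).
- The latency rule is this package's own; estimates carry its parameters
  and should not be compared to latencies from other rules without
  checking conventions.
- The behavioral training task itself is not modelled; `training_gain`
  reproduces only its hypothesised effect on TE contrast.
- Passing tests on synthetic data show the chain recovers the generative
  structure it assumes; they cannot show that real IT data satisfy those
  assumptions.
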