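# popsep

Population decoding and category-separation analysis for trial-aligned
spike recordings from macaque inferior temporal cortex (areas TEO and TE).

Neurons in IT carry visual category information, and the two IT
subdivisions appear to process it differently: a temporally stable code in
posterior TEO versus a category signal in anterior TE that grows within a
trial and strengthens with category training. `popsep` implements the full
analysis chain used to quantify that contrast from passive-fixation
recordings of cat and dog images, plus a generative spike-train simulator
so the chain can be validated end-to-end when raw recordings are not
available.

The chain:

1. **Visual responsiveness** — per neuron×image, a two-sided paired t-test
   on per-trial firing rates (baseline `[-200, 0)` vs stimulus `[0, 350)`
   ms), Benjamini–Hochberg FDR control within each neuron's image family,
   and classification as `only_dog` / `only_cat` / `both` / `none`.
   Gaussian-kernel (10 ms) firing-rate functions and onset-latency
   estimates.
2. **Population vectors** — per image, the N-vector of trial-averaged
   rates in a sliding 100-ms window; pseudo-populations pooled across
   sessions/animals by shared image identity.
3. **Decoding** — logistic regression `y(Φ) = σ(wᵀΦ)` fitted by
   minimising the cross-entropy error `E(w) = -Σ_n {t_n ln σ(wᵀφ_n) +
   (1-t_n) ln(1-σ(wᵀφ_n))}` (weak ridge by default), scored by stratified
   10-fold cross-validation per window → accuracy time courses.
4. **Separation** — Fisher LDA: `J(w) = wᵀS_B w / wᵀS_W w`, maximised by
   `ŵ ∝ S_W⁻¹(m₂-m₁)`, with category separation quantified as the
   Mahalanobis distance `D = sqrt((m₂-m₁)ᵀ S_W⁻¹ (m₂-m₁))`
   (`J(ŵ) = λ = D²`) → separation time courses and 1-D projections.
5. **Comparisons** — paired t-tests between accuracy curves (paired by
   window start), Mann–Whitney U-tests between window ranges of D
   (`[0, 100]` vs `[250, 350]` ms starts), two-proportion z-tests on
   responsive-neuron fractions.

The simulator draws inhomogeneous-Poisson trains with rate
`λ(t) = max(0, b + 1[t≥L](g + s·c·p(t) + ε))`; a `step` contrast profile
emulates the TEO-like flat representation, a `ramp` profile the TE-like
within-trial growth, and `training_gain` the post-training strengthening.
`expected_window_separation()` gives the closed-form expected D for any
window, which the empirical pipeline recovers within a few percent.

## Worked example

```r
library(popsep)

cfg <- synthetic_config(n_neurons = 40, images_per_category = 30,
                        trials_per_image = 10, profile = "ramp",
                        training_gain = 1.5, area = "TE", session = "post",
                        analysis_window = c(-300, 450), seed = 7)
d <- generate_dataset(cfg)
d
#> <spike_dataset> TE/post monkey=sim
#>   40 neurons, 60 images (30 cat / 30 dog), 600 trials, 196224 spikes
#>   analysis window [-300, 450) ms

summarize_responsiveness(responsiveness_counts(classify_neurons(d)))
#>   n_total n_responsive pct_responsive pct_rounded
#> 1      40           38             95          95

wins <- sliding_windows(-100, 300, width = 100, step = 50)
dec <- decoding_timecourse(d, wins, k = 10, seed = 1)
round(dec$accuracy, 3)
#> [1] 0.483 0.400 0.433 0.650 0.750 0.833 0.950 1.000 1.000

sep <- separation_timecourse(d, wins)
round(sep$D, 2)
#> [1] 0.39 0.37 0.30 0.59 0.63 0.86 1.63 1.46 1.73

tc <- separation_timecourse(d, rbind(sliding_windows(0, 100, 100, 1),
                                     sliding_windows(250, 350, 100, 1)))
mannwhitney_windows(tc, c(0, 100), c(250, 350), "greater")
#> <comparison_report> Mann-Whitney U-test (window-start ranges): [250,350] vs [0,100]
#>   statistic = 10201, p = 6.021e-35 (greater), n = 101/101
```

Read bottom to top: 95% of simulated TE neurons are visually responsive;
decoding accuracy sits at chance before stimulus onset and climbs through
the presentation (the ramping category signal); the Mahalanobis separation
D grows likewise, and the late windows (starts 250–350 ms) carry
significantly more category separation than the early ones (starts
0–100 ms) — the TE signature. A `profile = "step"` config instead
plateaus shortly after the ~60 ms response latency — the TEO signature.

A complete four-cell study (TEO/TE × pre/post) runs from one YAML config:

```r
res <- run_pipeline(read_run_config(demo_config_path()), "demo_out")
```

writing per-cell responsiveness tables, decoding and separation time
courses, all comparison reports, and a deterministic `report.json`.

Published neuron-classification counts for the three recorded macaques are
bundled (`macaque_response_counts()`), so pooled responsiveness
percentages can be reproduced without the raw recordings.

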