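# Four-cell demonstration run: TEO/TE x pre/post at reduced scale.
# TEO cells carry a temporally flat (step) category signal; TE cells a
# within-trial ramp, strengthened after category training (training_gain).
seed: 42
start_min: -100
start_max: 350
width: 100
step: 5
k: 5
lambda: 1
inversion: ridge
alpha: 0.05
baseline_window: [-200, 0]
stimulus_window: [0, 350]
contrast_early: [0, 100]
contrast_late: [250, 350]
cells:
  teo_pre:
    synthetic:
      n_neurons: 30
      images_per_category: 30
      trials_per_image: 5
      profile: step
      category_contrast: 5
      training_gain: 1
      area: TEO
      session: pre
      analysis_window: [-300, 450]
  teo_post:
    synthetic:
      n_neurons: 30
      images_per_category: 30
      trials_per_image: 5
      profile: step
      category_contrast: 5
      training_gain: 1
      area: TEO
      session: post
      analysis_window: [-300, 450]
  te_pre:
    synthetic:
      n_neurons: 30
      images_per_category: 30
      trials_per_image: 5
      profile: ramp
      category_contrast: 5
      training_gain: 1
      area: TE
      session: pre
      analysis_window: [-300, 450]
  te_post:
    synthetic:
      n_neurons: 30
      images_per_category: 30
      trials_per_image: 5
      profile: ramp
      category_contrast: 5
      training_gain: 1.5
      area: TE
      session: post
      analysis_window: [-300, 450]
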