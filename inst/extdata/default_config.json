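{
  "comment": "Default study configuration. Cohort and rater parameters are calibration choices of the simulator, not measured quantities: the rater panel is tuned so that rater-vs-reference agreement falls in the weak band before training and improves after, with one rater (P4) whose training response is negative. The impact prevalences are assumptions back-solved from the headline decision-tree percentages.",
  "cohort": {
    "n_reference": 1000,
    "mean_log_density": {
      "CD3.CT": 6.2146,
      "CD3.IM": 6.6846,
      "CD8.CT": 5.2983,
      "CD8.IM": 5.9915
    },
    "sd_log_density": 0.9,
    "corr_markers": 0.7,
    "corr_regions": 0.5,
    "seed": 1
  },
  "raters": [
    {"rater_id": "P1", "bias": 0,   "noise_sd": 30, "tau_low": 48, "tau_high": 85, "learning_rate": 0.8,  "noise_shrink": 0.6},
    {"rater_id": "P2", "bias": -12, "noise_sd": 24, "tau_low": 8,  "tau_high": 55, "learning_rate": 0.6,  "noise_shrink": 0.7},
    {"rater_id": "P3", "bias": 10,  "noise_sd": 26, "tau_low": 45, "tau_high": 80, "learning_rate": 0.9,  "noise_shrink": 0.5},
    {"rater_id": "P4", "bias": 12,  "noise_sd": 30, "tau_low": 48, "tau_high": 78, "learning_rate": -0.3, "noise_shrink": 1.1}
  ],
  "repeats": {
    "n_repeats": 3,
    "measurement_sd": 1.5,
    "seed": 1
  },
  "selection": {
    "n_per_bin": 5,
    "n_per_side": 10
  },
  "impact": {
    "annual_stage2": 101420,
    "annual_stage3": 23000,
    "p_lowrisk_given_stage2": 0.5294117647058824,
    "p_islow_given_lowrisk2": 0.2266666666666667,
    "p_ishigh_relevant2": 0.3333333333333333,
    "p_highclin_given_stage3": 0.4054054054054054,
    "p_islow_given_highclin3": 0.4933333333333333
  }
}
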