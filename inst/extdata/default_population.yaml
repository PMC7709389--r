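# Default synthetic serum population for the extended lipid panel generator.
#
# Nine lipoprotein subclasses (3 VLDL, 3 LDL, 3 HDL, large -> small within a
# class). Composition coefficients are mg/dL of analyte contributed per
# concentration unit of the subclass; signal amplitudes are per mg/dL of
# (cholesterol + triglyceride) carried. All spectral constants (line centers,
# linewidths, amplitudes, nuisance signals, baseline) are artifact choices of
# this generator, not measured lipoprotein parameters.
profiles:
  - {name: V1, ch3_center: 0.880, ch2_center: 1.300, linewidth: 0.025, chol_coeff: 6.0, tg_coeff: 26.0, apob_coeff: 5.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: V2, ch3_center: 0.868, ch2_center: 1.288, linewidth: 0.024, chol_coeff: 6.0, tg_coeff: 16.0, apob_coeff: 4.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: V3, ch3_center: 0.856, ch2_center: 1.276, linewidth: 0.022, chol_coeff: 5.0, tg_coeff: 9.0, apob_coeff: 3.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: L1, ch3_center: 0.840, ch2_center: 1.260, linewidth: 0.018, chol_coeff: 38.0, tg_coeff: 5.0, apob_coeff: 25.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: L2, ch3_center: 0.828, ch2_center: 1.248, linewidth: 0.017, chol_coeff: 33.0, tg_coeff: 5.0, apob_coeff: 25.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: L3, ch3_center: 0.816, ch2_center: 1.236, linewidth: 0.016, chol_coeff: 30.0, tg_coeff: 4.0, apob_coeff: 22.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: H1, ch3_center: 0.800, ch2_center: 1.220, linewidth: 0.013, chol_coeff: 20.0, tg_coeff: 3.5, apob_coeff: 0.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: H2, ch3_center: 0.790, ch2_center: 1.210, linewidth: 0.012, chol_coeff: 18.0, tg_coeff: 3.0, apob_coeff: 0.0, ch3_amp: 1.0, ch2_amp: 2.2}
  - {name: H3, ch3_center: 0.780, ch2_center: 1.200, linewidth: 0.011, chol_coeff: 16.0, tg_coeff: 2.5, apob_coeff: 0.0, ch3_amp: 1.0, ch2_amp: 2.2}
population:
  # per-subclass log-normal parameters (natural log scale); order V1..H3
  log_mean: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0]
  log_sd:   [0.80, 0.80, 0.75, 0.32, 0.32, 0.30, 0.28, 0.28, 0.26]
  # correlations on the log scale: within-class blocks plus
  # VLDL-LDL, VLDL-HDL (negative: hypertriglyceridemia depletes HDL), LDL-HDL
  cor_within_vldl: 0.75
  cor_within_ldl: 0.70
  cor_within_hdl: 0.70
  cor_vldl_ldl: 0.15
  cor_vldl_hdl: -0.40
  cor_ldl_hdl: 0.05
  # hypertriglyceridemic stratum: Bernoulli(fraction) membership; members get
  # the VLDL log-means shifted up and are constrained to TG >= threshold,
  # non-members to TG < threshold
  hyper_tg_fraction: 0.15
  hyper_tg_shift: 1.1
  tg_threshold: 250.0
spectrum:
  # rendered ppm axis (descending), at about 2.2x the canonical resolution
  ppm_max: 1.70
  ppm_min: 0.40
  n_points: 4096
  # nuisance signals: sharp lactate / alanine doublets and a BCAA methyl
  # multiplet cluster; amplitudes are median peak heights, varied per sample
  # by a log-normal factor with the stated log-SD
  lactate_amp: 40.0
  alanine_amp: 15.0
  bcaa_amp: 25.0
  nuisance_width: 0.004
  nuisance_log_sd: 0.40
  doublet_split: 0.0175
  bcaa_centers: [0.902, 0.928, 0.955, 1.005, 1.040]
  bcaa_rel: [1.0, 0.8, 0.6, 0.5, 0.4]
  # baseline polynomial b0 + b1*(ppm-1) + b2*(ppm-1)^2, fixed per config
  baseline: [8.0, -2.0, 1.5]
  # Gaussian noise SD as a fraction of the median peak height of the sample's
  # lipid + nuisance lines; line-center jitter SD in ppm
  noise_sd: 0.005
  ppm_jitter_sd: 0.002
seed: 42
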