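# Central intervention parameters (2011 NZ$) with 95% intervals / SDs.
uptake_cascade:
  p_smartphone: {central: 0.7442, lo: 0.5749, hi: 0.8819}
  p_exposed: {central: 0.7794, lo: 0.70, hi: 0.89}
  p_download: {central: 0.1346, lo: 0.025, hi: 0.25}
  p_regular_use: {central: 0.26, sd_fraction_of_mean: 0.20}
effect_size_kg: {central: -0.43, lo: -0.61, hi: -0.25}
bmi_decay_units_per_month: {central: 0.03, sd_fraction_of_mean: 0.20}
cost_components_nzd:
  web_promotion: 72000
  mass_media: 2791000
  app_identification: 20000
total_cost_nzd: 2883000
cost_uncertainty: {sd_fraction_of_mean: 0.20, correlation_with_uptake: 0.75}
ppp_nzd_per_usd: 1.486
threshold_nzd_per_qaly: 45000
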