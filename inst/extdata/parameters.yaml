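# PSA parameter specifications.
# family: beta | gamma | lognormal | normal | uniform
# uncertainty: sd, or a 95% interval (lo, hi) with sd = (hi - lo)/3.92
# lower/upper: hard domain clamps applied after sampling
# correlation_group: parameters sharing a label are sampled with Spearman
#   correlation 0.75 through a Gaussian copula
# group: tornado group label
parameters:
  - name: p_smartphone
    family: beta
    central: 0.7442
    lo: 0.5749
    hi: 0.8819
    correlation_group: intervention_uptake
    group: smartphone_access
  - name: p_exposed
    family: beta
    central: 0.7794
    lo: 0.70
    hi: 0.89
    correlation_group: intervention_uptake
    group: campaign_exposure
  - name: p_download
    family: beta
    central: 0.1346
    lo: 0.025
    hi: 0.25
    correlation_group: intervention_uptake
    group: app_downloaded
  - name: p_regular_use
    family: beta
    central: 0.26
    sd: 0.052
    group: regular_use
  - name: effect_kg
    family: normal
    central: -0.43
    lo: -0.61
    hi: -0.25
    upper: 0
    group: effect_size
  - name: decay_rate
    family: lognormal
    central: 0.03
    sd: 0.006
    group: bmi_decay
  - name: intervention_cost
    family: gamma
    central: 2883000
    sd: 576600
    correlation_group: intervention_uptake
    group: intervention_costs
  - name: tmrel_frac
    family: uniform
    central: 0
    lo: 0
    hi: 1
    group: tmrel
  - name: lag_nc_upper
    family: normal
    central: 5
    sd: 1
    lower: 1
    group: time_lags
  - name: lag_ca_lower
    family: normal
    central: 10
    sd: 2
    lower: 1
    group: time_lags
  - name: lag_ca_upper
    family: normal
    central: 30
    sd: 6
    lower: 2
    group: time_lags
  - name: rr_scale
    family: normal
    central: 1
    sd: 0.1
    lower: 0
    group: relative_risks
  - name: inc_mult
    family: lognormal
    central: 1
    sd: 0.05
    group: disease_rates
  - name: cf_mult
    family: lognormal
    central: 1
    sd: 0.05
    group: disease_rates
  - name: rem_mult
    family: lognormal
    central: 1
    sd: 0.05
    group: disease_rates
  - name: pyld_mult
    family: lognormal
    central: 1
    sd: 0.10
    group: morbidity
  - name: dr_mult
    family: normal
    central: 1
    sd: 0.10
    lower: 0
    group: morbidity
  - name: hs_cost_mult
    family: gamma
    central: 1
    sd: 0.10
    group: health_system_costs
  - name: trend_shift
    family: normal
    central: 0
    sd: 0.005
    group: trends
  - name: trend_shift_diabetes
    family: normal
    central: 0
    sd: 0.015
    group: trends
  - name: height_shift
    family: normal
    central: 0
    sd: 0.01
    group: heights
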