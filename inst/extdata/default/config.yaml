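exposure:
  net_consumption_reduction: 0.1152
  dmft_slope_per_10g: 0.01
  grams_sugar_per_cup: 26.0
  min_ssb_age: 2.0
  effectiveness_decay: 1.0
  net_consumption_reduction_sd: 0.0962
  dmft_slope_per_10g_sd: 0.028
epidemiology:
  teeth_per_case: 1.64
  dw_caries: 0.01
  dw_edentulism: 0.067
  caries_duration_child_days: 28.0
  caries_duration_adult_days: 55.0
  adult_age_cutoff: 17.0
  teeth_per_case_sd: 1.262
  dw_caries_sd: 0.004
  dw_edentulism_sd: 0.008
costs:
  cost_checkup: 54.689999999999998
  cost_restoration: 189.610000000000014
  cost_denture_pair: 2798.079999999999927
  denture_survival_10y: 0.41
  cost_travel_per_visit: 20.710000000000001
  time_value_per_hour: 49.219999999999999
  minutes_travel_per_visit: 60.0
  minutes_treatment_caries: 60.0
  minutes_treatment_denture: 60.0
  denture_visits: 3.0
  denture_minutes_mode: total
  restoration_cost_mode: per_tooth
  private_care_share: 0.85
  intervention_cost_year1: 5800000.0
  intervention_cost_subsequent: 4470000.0
  cost_checkup_sd: 3.19
  cost_restoration_sd: 17.949999999999999
  cost_denture_pair_sd: 433.370000000000005
  denture_survival_10y_sd: 0.064
  intervention_cost_year1_sd: 679000.0
  intervention_cost_subsequent_sd: 679000.0
settings:
  discount_rate: 0.03
  wtp_per_daly: 50000.0
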