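# SYNTHETIC demo device profiles for the study simulator.
#
# These eleven entries span the qualitative behaviors seen across
# point-of-care glucometer panels — small vs large relative bias, negative
# hematocrit interference, loss of precision at low glucose, under-range
# ("lo") displays, occasional device-error codes, mmol/L reporting, and the
# consumable cost tiers used by the ranking rule. They are invented demo
# parameters for simulation and documentation only; they are NOT measured
# characteristics of any real product, and device names are generic.
profiles:
  - device_model: "meterA-hosp"        # hospital-grade, high cost, accurate
    base_bias_pct: -2
    hct_coeff_pct_per_hct: -0.05
    sigma_low_pct: 6
    sigma_high_pct: 3
    cost_tier: exceeds_2_3x
  - device_model: "meterB-hosp"
    base_bias_pct: -1
    hct_coeff_pct_per_hct: -0.05
    sigma_low_pct: 5
    sigma_high_pct: 3
    cost_tier: exceeds_2_3x
  - device_model: "meterC-home"        # accurate low-cost home meters
    base_bias_pct: 2
    hct_coeff_pct_per_hct: -0.02
    sigma_low_pct: 4
    sigma_high_pct: 2.5
    cost_tier: meets_TPP
  - device_model: "meterD-home"
    base_bias_pct: 2
    hct_coeff_pct_per_hct: -0.02
    sigma_low_pct: 4
    sigma_high_pct: 2.5
    cost_tier: meets_TPP
  - device_model: "meterE-mmol"        # accurate but reports mmol/L
    base_bias_pct: 4
    hct_coeff_pct_per_hct: -0.05
    sigma_low_pct: 4
    sigma_high_pct: 2.5
    reads_mmol: true
    cost_tier: meets_TPP
  - device_model: "meterF-home"
    base_bias_pct: 5
    hct_coeff_pct_per_hct: -0.05
    sigma_low_pct: 4
    sigma_high_pct: 2.5
    cost_tier: unknown
  - device_model: "meterG-optical"     # optical method, hct-sensitive
    base_bias_pct: -4
    hct_coeff_pct_per_hct: -0.15
    sigma_low_pct: 8
    sigma_high_pct: 5
    cost_tier: meets_TPP
  - device_model: "meterH-underread"   # underestimates at high glucose/hct
    base_bias_pct: -9
    hct_coeff_pct_per_hct: -0.2
    sigma_low_pct: 8
    sigma_high_pct: 6
    cost_tier: unknown
  - device_model: "meterI-hctsens"     # strong hct interference, imprecise
    base_bias_pct: 5
    hct_coeff_pct_per_hct: -0.35
    sigma_low_pct: 15
    sigma_high_pct: 8
    cost_tier: unknown
  - device_model: "meterJ-lowfloor"    # precise at high, very poor at low
    base_bias_pct: 2
    hct_coeff_pct_per_hct: 0
    sigma_low_pct: 20
    sigma_high_pct: 5
    error_rate: 0.036
    reads_mmol: true
    display_floor: 20
    cost_tier: unknown
  - device_model: "meterK-cuvette"     # cuvette meter, errors + low-gluc scatter
    base_bias_pct: 0
    hct_coeff_pct_per_hct: -0.3
    sigma_low_pct: 18
    sigma_high_pct: 4
    error_rate: 0.033
    cost_tier: exceeds_2_3x
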