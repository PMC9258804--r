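settings:
  discount_rate: 0.05
  wtp: 7142.0
  stroke_from_nsr: no
  half_cycle_correction: no
  reward_timing: end
  default_sd_probability: 0.2
  default_sd_cost: 0.1
shared:
  cost_af_annual:
    base: 372.81
    sd: 55.92
    dist: gamma
    low: 260.97
    high: 484.65
  cost_nsr_annual:
    base: 273.32
    sd: 40.99
    dist: gamma
    low: 191.34
    high: 355.3
  cost_stroke_y1:
    base: 1804.49
    sd: 180.44
    dist: gamma
    low: 1443.61
    high: 2165.37
  cost_poststroke:
    base: 541.34
    sd: 54.13
    dist: gamma
    low: 433.08
    high: 649.6
  u_nsr:
    base: 0.8
    sd: 0.00577
    dist: beta
    low: 0.78846
    high: 0.81154
  u_af:
    base: 0.6
    sd: 0.0721
    dist: beta
    low: 0.4558
    high: 0.7442
  u_poststroke:
    base: 0.46
    sd: 0.0577
    dist: beta
    low: 0.3446
    high: 0.5754
  du_complication:
    base: -0.0314
    sd: 0.00628
    dist: beta
    low: -0.04396
    high: -0.01884
  du_stroke_y1:
    base: -0.296
    sd: 0.0592
    dist: beta
    low: -0.4144
    high: -0.1776
  p_op_death:
    base: 0.000487
    sd: 9.74e-05
    dist: beta
    low: 0.0002922
    high: 0.0006818
  p_stroke_death:
    base: 0.3536
    sd: 0.07072
    dist: beta
    low: 0.21216
    high: 0.49504
  start_age:
    base: 50.0
    dist: fixed
    low: 50.0
    high: 50.0
cba:
  p_recur_y1:
    base: 0.269
    sd: 0.0538
    dist: beta
    low: 0.1614
    high: 0.3766
  p_recur_late:
    base: 0.0938
    sd: 0.0235
    dist: beta
    low: 0.0468
    high: 0.1408
  p_redo_rfa:
    base: 0.5516
    sd: 0.11032
    dist: beta
    low: 0.33096
    high: 0.77224
  p_redo_cba:
    base: 0.0951
    sd: 0.01902
    dist: beta
    low: 0.05706
    high: 0.13314
  p_pericardial:
    base: 0.0084
    sd: 0.00168
    dist: beta
    low: 0.00504
    high: 0.01176
  p_phrenic:
    base: 0.032
    sd: 0.0064
    dist: beta
    low: 0.0192
    high: 0.0448
  p_vascular:
    base: 0.0156
    sd: 0.00312
    dist: beta
    low: 0.00936
    high: 0.02184
  p_stroke:
    base: 0.05
    sd: 0.01
    dist: beta
    low: 0.03
    high: 0.07
  cost_procedure:
    base: 7751.88
    sd: 516.72
    dist: gamma
    low: 6718.44
    high: 8785.32
  cost_pericardial:
    base: 1060.19
    sd: 106.01
    dist: gamma
    low: 848.17
    high: 1272.21
  cost_phrenic:
    base: 11.09
    sd: 1.109
    dist: gamma
    low: 8.872
    high: 13.308
  cost_vascular:
    base: 60.23
    sd: 6.023
    dist: gamma
    low: 48.184
    high: 72.276
rfa:
  p_recur_y1:
    base: 0.3326
    sd: 0.0665
    dist: beta
    low: 0.1996
    high: 0.4656
  p_recur_late:
    base: 0.1055
    sd: 0.0264
    dist: beta
    low: 0.0527
    high: 0.1583
  p_redo_rfa:
    base: 0.5685
    sd: 0.1137
    dist: beta
    low: 0.3411
    high: 0.7959
  p_redo_cba:
    base: 0.0587
    sd: 0.01174
    dist: beta
    low: 0.03522
    high: 0.08218
  p_pericardial:
    base: 0.0231
    sd: 0.00462
    dist: beta
    low: 0.01386
    high: 0.03234
  p_phrenic:
    base: 0.0005
    sd: 0.0001
    dist: beta
    low: 0.0003
    high: 0.0007
  p_vascular:
    base: 0.023
    sd: 0.0046
    dist: beta
    low: 0.0138
    high: 0.0322
  p_stroke:
    base: 0.05
    sd: 0.01
    dist: beta
    low: 0.03
    high: 0.07
  cost_procedure:
    base: 5027.1
    sd: 1530.66
    dist: gamma
    low: 1965.78
    high: 8088.42
  cost_pericardial:
    base: 1060.19
    sd: 106.01
    dist: gamma
    low: 848.17
    high: 1272.21
  cost_phrenic:
    base: 11.09
    sd: 1.109
    dist: gamma
    low: 8.872
    high: 13.308
  cost_vascular:
    base: 60.23
    sd: 6.023
    dist: gamma
    low: 48.184
    high: 72.276
life_table: iran_life_table_synthetic.csv
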