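groups:
  group:
  - ASD
  - AS
  - CdLS
  - DS
  - FXS
  - PMS
  - PWS
  - RTT
  - RTS
  - SMS
  - Soto
  - TSC
  - 1p36
  - 8p23
  'n':
  - 66
  - 28
  - 44
  - 29
  - 102
  - 31
  - 101
  - 87
  - 47
  - 20
  - 38
  - 71
  - 26
  - 22
  child_age_mean:
  - 15.5
  - 10.9
  - 12.8
  - 25.4
  - 15.0
  - 11.3
  - 12.2
  - 20.1
  - 21.3
  - 11.6
  - 15.3
  - 18.8
  - 10.9
  - 10.8
  child_age_sd:
  - 6.5
  - 3.3
  - 8.2
  - 11.8
  - 8.2
  - 8.4
  - 8.1
  - 10.2
  - 10.5
  - 7.2
  - 9.3
  - 10.7
  - 8.9
  - 5.5
  maternal_age_mean:
  - 47.9
  - 40.8
  - 45.1
  - 59.1
  - 45.6
  - 42.3
  - 44.5
  - 50.7
  - 49.8
  - 43.7
  - 46.3
  - 48.1
  - 41.2
  - 39.6
  maternal_age_sd:
  - 6.8
  - 4.9
  - 9.1
  - 12.3
  - 9.5
  - 9.9
  - 8.5
  - 9.2
  - 9.9
  - 8.5
  - 8.3
  - 10.3
  - 10.8
  - 6.1
  p_male:
  - 0.864
  - 0.464
  - 0.477
  - 0.533
  - 1.0
  - 0.452
  - 0.523
  - 0.0
  - 0.553
  - 0.6
  - 0.684
  - 0.606
  - 0.786
  - 0.682
  p_wessex_max:
  - 0.892
  - 0.143
  - 0.409
  - 0.9
  - 0.882
  - 0.226
  - 0.782
  - 0.1
  - 0.809
  - 0.6
  - 0.842
  - 0.662
  - 0.423
  - 0.591
outcome_effects:
  pgs:
    base: 21.66
    shift:
      AS: -0.11
      CdLS: 0.0
      DS: 0.76
      FXS: 0.0
      PMS: 1.32
      PWS: -0.6
      RTT: 1.05
      RTS: 1.04
      SMS: 0.04
      Soto: 0.12
      TSC: -0.02
      1p36: -0.02
      8p23: 0.23
    child_age: -0.05
    maternal_age: -0.04
    wessex_max: 0.0
    interactions:
    - groups:
      - DS
      - RTS
      - PMS
      - RTT
      maternal_age: -0.04
    noise_sd: 3.3
  pas5:
    base: 15.25
    shift:
      AS: 1.35
      CdLS: 0.26
      DS: 0.68
      FXS: 0.52
      PMS: 0.78
      PWS: 0.4
      RTT: 1.98
      RTS: -0.18
      SMS: 0.37
      Soto: 0.28
      TSC: 0.07
      1p36: 0.38
      8p23: 1.61
    child_age: 0.0
    maternal_age: -0.06
    wessex_max: 0.0
    interactions: []
    noise_sd: 2.1
  hads:
    base: 7.12
    shift:
      AS: -1.09
      CdLS: -0.2
      DS: -2.33
      FXS: -1.51
      PMS: -0.99
      PWS: -1.0
      RTT: -2.42
      RTS: -1.76
      SMS: 0.54
      Soto: -1.7
      TSC: -1.24
      1p36: -0.16
      8p23: -2.3
    child_age: 0.0
    maternal_age: 0.0
    wessex_max: 0.0
    interactions:
    - groups:
      - AS
      - FXS
      - PWS
      - TSC
      - PMS
      wessex_max: -1.8
    noise_sd: 4.2
  stress:
    base: 5.7
    shift:
      AS: -1.0
      CdLS: -1.0
      DS: -3.0
      FXS: -2.0
      PMS: -1.0
      PWS: -2.0
      RTT: -2.0
      RTS: -1.0
      SMS: 0.0
      Soto: -2.0
      TSC: -1.0
      1p36: -1.0
      8p23: -2.0
    child_age: 0.04
    maternal_age: 0.0
    wessex_max: -1.0
    interactions:
    - groups:
      - Soto
      - AS
      - SMS
      child_age: -0.1
    noise_sd: 1.5
missing_item_rate: 0.02
p_nonmother: 0.0
wessex_range:
- 3
- 9
scq:
  mean: 22.0
  sd: 5.0
  min: 15.0
  max: 39.0
age_centres:
  child: 15.0
  maternal: 47.0
seed: 2.0181025e+07
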