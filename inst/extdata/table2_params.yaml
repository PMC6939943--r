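costs:
  bdmard:
    base: 14834.0
    dsa_low: 8147.0
    dsa_high: 21520.0
    psa:
      dist: gamma
      mean: 14834.0
      sd: 6687.0
  csdmard:
    base: 1086.0
    dsa_low: 596.0
    dsa_high: 1575.0
    psa:
      dist: gamma
      mean: 1086.0
      sd: 490.0
  concomitant:
    base: 45.0
    dsa_low: 25.0
    dsa_high: 65.0
    psa:
      dist: gamma
      mean: 45.0
      sd: 20.0
  other_direct:
    le64:
      REM:
        base: 1495.0
        dsa_low: 821.0
        dsa_high: 2168.0
        psa:
          dist: gamma
          mean: 1760.0
          sd: 793.0
      LDA:
        base: 2316.0
        dsa_low: 1272.0
        dsa_high: 3360.0
        psa:
          dist: gamma
          mean: 2386.0
          sd: 1068.0
      MHDA:
        base: 3713.0
        dsa_low: 2039.0
        dsa_high: 5387.0
        psa:
          dist: gamma
          mean: 3797.0
          sd: 1712.0
    gt65:
      REM:
        base: 2024.0
        dsa_low: 1112.0
        dsa_high: 2936.0
        psa:
          dist: gamma
          mean: 1760.0
          sd: 793.0
      LDA:
        base: 2421.0
        dsa_low: 1330.0
        dsa_high: 3512.0
        psa:
          dist: gamma
          mean: 2386.0
          sd: 1068.0
      MHDA:
        base: 3881.0
        dsa_low: 2132.0
        dsa_high: 5630.0
        psa:
          dist: gamma
          mean: 3797.0
          sd: 1712.0
utilities:
  REM:
    base: 0.75
    dsa_low: 0.69
    dsa_high: 0.81
    psa:
      dist: beta
      alpha: 0.7133
      beta: 0.2378
  LDA:
    base: 0.71
    dsa_low: 0.68
    dsa_high: 0.74
    psa:
      dist: beta
      alpha: 0.8112
      beta: 0.3313
  MHDA:
    base: 0.6
    dsa_low: 0.57
    dsa_high: 0.64
    psa:
      dist: beta
      alpha: 0.8984
      beta: 0.599
  decrement_full_dose: 0.0567
  decrement_half_dose: 0.0284
transitions:
  standard.REM:
    dirichlet:
    - 111.0
    - 8.0
    - 6.0
    cells:
      REM:
        base: 0.8911
        dsa_low: 0.8457
        dsa_high: 0.9585
      LDA:
        base: 0.0666
        dsa_low: 0.0039
        dsa_high: 0.091
      MHDA:
        base: 0.0491
        dsa_low: 0.0
        dsa_high: 0.1048
  standard.LDA:
    dirichlet:
    - 126.0
    - 245.0
    - 10.0
    cells:
      REM:
        base: 0.3291
        dsa_low: 0.1702
        dsa_high: 0.4879
      LDA:
        base: 0.639
        dsa_low: 0.5079
        dsa_high: 0.77
      MHDA:
        base: 0.0256
        dsa_low: 0.008
        dsa_high: 0.0431
  standard.MHDA:
    dirichlet:
    - 843.0
    - 429.0
    - 3499.0
    cells:
      REM:
        base: 0.176
        dsa_low: 0.129
        dsa_high: 0.2219
      LDA:
        base: 0.0895
        dsa_low: 0.0593
        dsa_high: 0.1196
      MHDA:
        base: 0.7305
        dsa_low: 0.6609
        dsa_high: 0.8015
  tapering.REM:
    dirichlet:
    - 55.0
    - 7.0
    - 5.0
    cells:
      REM:
        base: 0.8733
        dsa_low: 0.7562
        dsa_high: 0.9903
      LDA:
        base: 0.1111
        dsa_low: 0.0085
        dsa_high: 0.2138
      MHDA:
        base: 0.0791
        dsa_low: 0.0125
        dsa_high: 0.1458
  tapering.LDA:
    dirichlet:
    - 45.0
    - 126.0
    - 5.0
    cells:
      REM:
        base: 0.2547
        dsa_low: 0.1946
        dsa_high: 0.3148
      LDA:
        base: 0.7216
        dsa_low: 0.6598
        dsa_high: 0.7834
      MHDA:
        base: 0.0237
        dsa_low: 0.0027
        dsa_high: 0.0447
  withdrawal.REM:
    dirichlet:
    - 136.0
    - 16.0
    - 30.0
    cells:
      REM:
        base: 0.7394
        dsa_low: 0.6411
        dsa_high: 0.8378
      LDA:
        base: 0.0843
        dsa_low: 0.032
        dsa_high: 0.1367
      MHDA:
        base: 0.1616
        dsa_low: 0.1012
        dsa_high: 0.222
  withdrawal.LDA:
    dirichlet:
    - 59.0
    - 243.0
    - 30.0
    cells:
      REM:
        base: 0.1764
        dsa_low: 0.0871
        dsa_high: 0.2656
      LDA:
        base: 0.7322
        dsa_low: 0.6897
        dsa_high: 0.7746
      MHDA:
        base: 0.0905
        dsa_low: 0.0086
        dsa_high: 0.1725
mortality:
  female_share: 0.75
  smr_mhda: 2.34
  start_age: 45.0
  cycle_one:
    rem_lda: 0.0008
    mhda: 0.0019
settings:
  cycle_months: 6.0
  horizon_years: 30.0
  annual_discount_rate: 0.03
  discount_dsa:
  - 0.0
  - 0.06
  horizon_dsa_cycles:
  - 40.0
  - 80.0
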