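schema: radoncrisk/risk_model_spec/v1
name: ICRP 103-like
sites:
- site: bladder
  sexes: both
  class: solid
- site: breast
  sexes: female
  class: solid
- site: colon
  sexes: both
  class: solid
- site: esophagus
  sexes: both
  class: solid
- site: liver
  sexes: both
  class: solid
- site: lung
  sexes: both
  class: solid
- site: other_solid
  sexes: both
  class: solid
- site: ovary
  sexes: female
  class: solid
- site: stomach
  sexes: both
  class: solid
- site: thyroid
  sexes: both
  class: solid
- site: leukemia
  sexes: both
  class: leukemia
w_ear: 0.5
w_err: 0.5
ddref: 2.0
latency_solid_years: 5.0
latency_leukemia_years: 2.0
combination: weighted_arithmetic
risk_measure: REIC
scaling: per_10000_per_Gy
leukemia_quadratic_theta_per_Gy2: 1.0
sex_averaged: no
coefficients:
- site: bladder
  sex: male
  pathway: ERR
  beta: 0.5
  gamma: -0.3
  eta: -1.4
- site: bladder
  sex: male
  pathway: EAR
  beta: 1.0
  gamma: -0.41
  eta: 2.8
- site: bladder
  sex: female
  pathway: ERR
  beta: 0.5
  gamma: -0.3
  eta: -1.4
- site: bladder
  sex: female
  pathway: EAR
  beta: 1.0
  gamma: -0.41
  eta: 2.8
- site: breast
  sex: female
  pathway: ERR
  beta: 0.5
  gamma: -0.3
  eta: -1.4
- site: breast
  sex: female
  pathway: EAR
  beta: 6.0
  gamma: -0.41
  eta: 2.8
- site: colon
  sex: male
  pathway: ERR
  beta: 0.6
  gamma: -0.3
  eta: -1.4
- site: colon
  sex: male
  pathway: EAR
  beta: 2.4
  gamma: -0.41
  eta: 2.8
- site: colon
  sex: female
  pathway: ERR
  beta: 0.6
  gamma: -0.3
  eta: -1.4
- site: colon
  sex: female
  pathway: EAR
  beta: 2.4
  gamma: -0.41
  eta: 2.8
- site: esophagus
  sex: male
  pathway: ERR
  beta: 0.4
  gamma: -0.3
  eta: -1.4
- site: esophagus
  sex: male
  pathway: EAR
  beta: 0.6
  gamma: -0.41
  eta: 2.8
- site: esophagus
  sex: female
  pathway: ERR
  beta: 0.4
  gamma: -0.3
  eta: -1.4
- site: esophagus
  sex: female
  pathway: EAR
  beta: 0.6
  gamma: -0.41
  eta: 2.8
- site: liver
  sex: male
  pathway: ERR
  beta: 0.35
  gamma: -0.3
  eta: -1.4
- site: liver
  sex: male
  pathway: EAR
  beta: 2.0
  gamma: -0.41
  eta: 2.8
- site: liver
  sex: female
  pathway: ERR
  beta: 0.35
  gamma: -0.3
  eta: -1.4
- site: liver
  sex: female
  pathway: EAR
  beta: 2.0
  gamma: -0.41
  eta: 2.8
- site: lung
  sex: male
  pathway: ERR
  beta: 0.4
  gamma: -0.3
  eta: -1.4
- site: lung
  sex: male
  pathway: EAR
  beta: 3.4
  gamma: -0.41
  eta: 2.8
- site: lung
  sex: female
  pathway: ERR
  beta: 0.4
  gamma: -0.3
  eta: -1.4
- site: lung
  sex: female
  pathway: EAR
  beta: 3.4
  gamma: -0.41
  eta: 2.8
- site: other_solid
  sex: male
  pathway: ERR
  beta: 0.3
  gamma: -0.3
  eta: -1.4
- site: other_solid
  sex: male
  pathway: EAR
  beta: 3.0
  gamma: -0.41
  eta: 2.8
- site: other_solid
  sex: female
  pathway: ERR
  beta: 0.3
  gamma: -0.3
  eta: -1.4
- site: other_solid
  sex: female
  pathway: EAR
  beta: 3.0
  gamma: -0.41
  eta: 2.8
- site: ovary
  sex: female
  pathway: ERR
  beta: 0.4
  gamma: -0.3
  eta: -1.4
- site: ovary
  sex: female
  pathway: EAR
  beta: 0.7
  gamma: -0.41
  eta: 2.8
- site: stomach
  sex: male
  pathway: ERR
  beta: 0.25
  gamma: -0.3
  eta: -1.4
- site: stomach
  sex: male
  pathway: EAR
  beta: 3.3
  gamma: -0.41
  eta: 2.8
- site: stomach
  sex: female
  pathway: ERR
  beta: 0.25
  gamma: -0.3
  eta: -1.4
- site: stomach
  sex: female
  pathway: EAR
  beta: 3.3
  gamma: -0.41
  eta: 2.8
- site: thyroid
  sex: male
  pathway: ERR
  beta: 0.5
  gamma: -0.3
  eta: -1.4
- site: thyroid
  sex: male
  pathway: EAR
  beta: 0.4
  gamma: -0.41
  eta: 2.8
- site: thyroid
  sex: female
  pathway: ERR
  beta: 0.5
  gamma: -0.3
  eta: -1.4
- site: thyroid
  sex: female
  pathway: EAR
  beta: 0.4
  gamma: -0.41
  eta: 2.8
- site: leukemia
  sex: male
  pathway: ERR
  beta: 1.1
  gamma: -0.4
  eta: -1.0
- site: leukemia
  sex: male
  pathway: EAR
  beta: 0.8
  gamma: -0.4
  eta: 1.0
- site: leukemia
  sex: female
  pathway: ERR
  beta: 1.1
  gamma: -0.4
  eta: -1.0
- site: leukemia
  sex: female
  pathway: EAR
  beta: 0.8
  gamma: -0.4
  eta: 1.0
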