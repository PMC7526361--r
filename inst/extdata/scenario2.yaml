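# Default study configuration, scenario 2 (menopausal status is both a
# prognostic factor and an effect modifier of treatment B). The total
# expected treatment effect equals scenario 1: -0.4 + (-0.2) * 0.5 = -0.5
# at the comparator's postmenopausal prevalence.
scenario: 2
n_reps: 200
seed: 1
risk_times: [0, 500, 1000, 1500, 2000, 2500]
surv_digits: 4
time_digits: 0
publish_events: yes
arm_a:
  "n": 1000
  age_mean: 53
  age_sd: 11
  age_range: [21, 80]
  p_postmenopausal: 0.40
  p_grade: [0.20, 0.65, 0.15]
  weibull_scale: 4.0e-8
  weibull_shape: 2.2
  beta_age: 0.02
  beta_meno: 0.5
  beta_grade2: 0.3
  beta_grade3: 0.6
  max_followup: 2500
  censor_upper: 2500
arm_b:
  "n": 800
  age_mean: 56
  age_sd: 12
  age_range: [23, 85]
  p_postmenopausal: 0.50
  p_grade: [0.10, 0.70, 0.20]
  weibull_scale: 4.0e-8
  weibull_shape: 2.2
  beta_age: 0.02
  beta_meno: 0.5
  beta_grade2: 0.3
  beta_grade3: 0.6
  beta_treatment: -0.4
  beta_interaction: -0.2
  max_followup: 2500
  censor_upper: 2500
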