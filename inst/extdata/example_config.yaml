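outcome_name: stroke
baseline_terms:
- age
- age2
- sex
- sbp0
time_terms:
- tt
- tt2
K_max: 7
visit_schedule:
- 0
- 2
- 5
visit_window_end:
- 3
- 6
n_sim: 2000
n_boot: 100
mode: competing
seed: 1
baseline_fields:
- person_id
- age
- sex
- sbp0
- mmse0
covariates:
- name: visit
  family: visit
  terms: ~
  bounds: ~
- name: sbp
  family: continuous
  terms: ~
  bounds: ~
- name: ht_med
  family: binary
  terms: ~
  bounds: ~
strategies:
- id: 0
  label: Natural course
  natural_course: yes
  rules: []
- id: 1
  label: Maintain SBP below 120 mmHg
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 120.0
    set: 120.0
    scale: ~
- id: 2
  label: Maintain SBP below 140 mmHg
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: 140.0
    scale: ~
- id: 3
  label: Reduce SBP by 10% if above 140 mmHg
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: ~
    scale: 0.9
- id: 4
  label: Reduce SBP by 20% if above 140 mmHg
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: ~
    scale: 0.8
- id: 5
  label: Quit smoking
  natural_course: no
  rules:
  - target: smoking
    when_var: smoking
    when_op: ==
    when_value: current
    set: former
    scale: ~
- id: 6
  label: Maintain SBP below 120 mmHg and quit smoking
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 120.0
    set: 120.0
    scale: ~
  - target: smoking
    when_var: smoking
    when_op: ==
    when_value: current
    set: former
    scale: ~
- id: 7
  label: Maintain SBP below 140 mmHg and quit smoking
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: 140.0
    scale: ~
  - target: smoking
    when_var: smoking
    when_op: ==
    when_value: current
    set: former
    scale: ~
- id: 8
  label: Reduce SBP by 10% if above 140 mmHg and quit smoking
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: ~
    scale: 0.9
  - target: smoking
    when_var: smoking
    when_op: ==
    when_value: current
    set: former
    scale: ~
- id: 9
  label: Reduce SBP by 20% if above 140 mmHg and quit smoking
  natural_course: no
  rules:
  - target: sbp
    when_var: sbp
    when_op: '>'
    when_value: 140.0
    set: ~
    scale: 0.8
  - target: smoking
    when_var: smoking
    when_op: ==
    when_value: current
    set: former
    scale: ~
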