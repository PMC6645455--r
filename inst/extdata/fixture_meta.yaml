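profile: paper-like
seed: 20190722
n_tips: 40.0
candidates:
- female_group_size
- male_group_size
- female_sexual_maturity
- life_span
- innovation
- fruit
mandatory: female_weight
outcomes:
- total_brain
- neocortex
beta_total_brain:
- 5.0
- 0.62
- 0.1
- -0.07
- 0.22
- 0.1
- 0.0
- 0.2
beta_neocortex:
- 4.2
- 0.58
- 0.22
- -0.1
- 0.18
- 0.15
- 0.0
- 0.0
sigma2: 0.022
lambda: 1.0
predictor_cor:
  female_weight:
    female_weight: 1.0
    female_group_size: 0.45
    male_group_size: 0.45
    female_sexual_maturity: 0.6
    life_span: 0.6
    innovation: 0.45
    fruit: 0.45
  female_group_size:
    female_weight: 0.45
    female_group_size: 1.0
    male_group_size: 0.75
    female_sexual_maturity: 0.45
    life_span: 0.45
    innovation: 0.45
    fruit: 0.45
  male_group_size:
    female_weight: 0.45
    female_group_size: 0.75
    male_group_size: 1.0
    female_sexual_maturity: 0.45
    life_span: 0.45
    innovation: 0.45
    fruit: 0.45
  female_sexual_maturity:
    female_weight: 0.6
    female_group_size: 0.45
    male_group_size: 0.45
    female_sexual_maturity: 1.0
    life_span: 0.65
    innovation: 0.45
    fruit: 0.45
  life_span:
    female_weight: 0.6
    female_group_size: 0.45
    male_group_size: 0.45
    female_sexual_maturity: 0.65
    life_span: 1.0
    innovation: 0.45
    fruit: 0.45
  innovation:
    female_weight: 0.45
    female_group_size: 0.45
    male_group_size: 0.45
    female_sexual_maturity: 0.45
    life_span: 0.45
    innovation: 1.0
    fruit: 0.35
  fruit:
    female_weight: 0.45
    female_group_size: 0.45
    male_group_size: 0.45
    female_sexual_maturity: 0.45
    life_span: 0.45
    innovation: 0.35
    fruit: 1.0
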