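genes:
  gene:
  - MAOB
  - NAB2
  - COL3A1
  - NPIPB4
  - CYP27A1
  - SIAE
  control_mean:
  - 4.01
  - 2.11
  - 1.55
  - 1.89
  - 1.57
  - 1.18
  control_sd:
  - 1.2
  - 0.42
  - 0.2
  - 0.26
  - 0.23
  - 0.24
  case_mean:
  - 0.7
  - 0.49
  - 0.62
  - 0.77
  - 0.68
  - 0.73
  case_sd:
  - 0.27
  - 0.05
  - 0.12
  - 0.14
  - 0.12
  - 0.11
  age_effect:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
n_control: 34
n_case: 33
age_model:
  control:
    mean: 53.200000000000003
    sd: 17.399999999999999
    min: 25.0
    max: 83.0
  case:
    mean: 61.200000000000003
    sd: 18.100000000000001
    min: 24.0
    max: 97.0
covariate_rates:
  control:
    male: 0.441176470588235
    smoking: 0.264705882352941
    alcohol: 0.382352941176471
    periodontitis: 0.088235294117647
  case:
    male: 0.666666666666667
    smoking: 0.272727272727273
    alcohol: 0.333333333333333
    periodontitis: 0.303030303030303
distribution: lognormal
seed: 1
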