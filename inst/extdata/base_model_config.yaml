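costs:
  resection: 17666.0
  ablation: 4895.0
  tace: 5708.0
  sorafenib_cycle: 4500.0
  transplant: 51779.0
  followup_post_curative_cycle: 146.0
  followup_post_tace_cycle: 379.0
  followup_post_transplant_cycle: 1514.0
  usd_per_eur: 1.1
discount:
  annual_rate: 0.03
  cycle_months: 3.0
  horizon_years: 20.0
weights:
  bondy:
    resection: 0.004
    ablation: 0.707
    tace: 0.177
    sorafenib: 0.112
  soc:
    resection: 0.132
    ablation: 0.24
    tace: 0.481
    sorafenib: 0.147
targets:
  bondy:
    resection:
      life_years: 19.899999999999999
      cost: 31750.0
    ablation:
      life_years: 15.700141442715701
      cost: 20492.220650636492792
    tace:
      life_years: 3.954802259887006
      cost: 12813.559322033899662
    sorafenib:
      life_years: 1.785714285714286
      cost: 11803.571428571427532
  soc:
    resection:
      life_years: 19.696969696969695
      cost: 33462.121212121208373
    ablation:
      life_years: 15.833333333333334
      cost: 20433.333333333335759
    tace:
      life_years: 8.93970893970894
      cost: 28020.790020790020208
    sorafenib:
      life_years: 3.401360544217687
      cost: 18326.530612244900112
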