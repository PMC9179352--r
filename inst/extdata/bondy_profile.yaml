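'n': 266
group: bondy
covariate_marginals:
  male:
    'TRUE': 0.804511278195489
    'FALSE': 0.195488721804511
  comorbidity_gt1:
    'TRUE': 0.037593984962406
    'FALSE': 0.962406015037594
  aetiology:
    alcohol: 0.424812030075188
    hcv: 0.334586466165414
    hbv: 0.12781954887218
    nash: 0.075187969924812
    other: 0.037593984962406
  child_pugh:
    A: 0.913533834586466
    B: 0.086466165413534
  portal_htn:
    'TRUE': 0.578947368421053
    'FALSE': 0.421052631578947
  afp_cat:
    le100: 0.710526315789474
    100to1000: 0.180451127819549
    gt1000: 0.109022556390977
  n_tumors_cat:
    '1': 0.620300751879699
    2_3: 0.236842105263158
    ge4: 0.142857142857143
  largest_mm_cat:
    le30: 0.432330827067669
    30to60: 0.338345864661654
    gt60: 0.229323308270677
  bilobar:
    'TRUE': 0.240601503759398
    'FALSE': 0.759398496240602
stage_distribution:
  very_early: 0.06015037593985
  early: 0.590225563909774
  intermediate: 0.206766917293233
  advanced: 0.142857142857143
allocation_policy:
  very_early:
    resection: 0.0
    ablation: 1.0
    tace: 0.0
    sorafenib: 0.0
  early:
    resection: 0.0
    ablation: 0.89171974522293
    tace: 0.089171974522293
    sorafenib: 0.019108280254777
  intermediate:
    resection: 0.018181818181818
    ablation: 0.381818181818182
    tace: 0.563636363636364
    sorafenib: 0.036363636363636
  advanced:
    resection: 0.0
    ablation: 0.289473684210526
    tace: 0.052631578947368
    sorafenib: 0.657894736842105
survival_medians:
  resection: 35.0
  ablation: 35.0
  tace: 12.0
  sorafenib: 4.0
censor_horizon_months: 84.0
missing_rate: ~
age_mean: 66.0
age_sd: 11.0
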