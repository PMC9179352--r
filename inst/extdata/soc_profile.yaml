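'n': 266
group: soc
covariate_marginals:
  male:
    'TRUE': 0.793233082706767
    'FALSE': 0.206766917293233
  comorbidity_gt1:
    'TRUE': 0.071428571428571
    'FALSE': 0.928571428571429
  aetiology:
    alcohol: 0.43984962406015
    hcv: 0.330827067669173
    hbv: 0.120300751879699
    nash: 0.082706766917293
    other: 0.026315789473684
  child_pugh:
    A: 0.917293233082707
    B: 0.082706766917293
  portal_htn:
    'TRUE': 0.548872180451128
    'FALSE': 0.451127819548872
  afp_cat:
    le100: 0.669172932330827
    100to1000: 0.18796992481203
    gt1000: 0.142857142857143
  n_tumors_cat:
    '1': 0.62406015037594
    2_3: 0.229323308270677
    ge4: 0.146616541353383
  largest_mm_cat:
    le30: 0.447368421052632
    30to60: 0.349624060150376
    gt60: 0.203007518796992
  bilobar:
    'TRUE': 0.240601503759398
    'FALSE': 0.759398496240602
stage_distribution:
  very_early: 0.082706766917293
  early: 0.548872180451128
  intermediate: 0.206766917293233
  advanced: 0.161654135338346
allocation_policy:
  very_early:
    resection: 0.0
    ablation: 1.0
    tace: 0.0
    sorafenib: 0.0
  early:
    resection: 0.23972602739726
    ablation: 0.23972602739726
    tace: 0.493150684931507
    sorafenib: 0.027397260273973
  intermediate:
    resection: 0.0
    ablation: 0.090909090909091
    tace: 0.909090909090909
    sorafenib: 0.0
  advanced:
    resection: 0.0
    ablation: 0.046511627906977
    tace: 0.13953488372093
    sorafenib: 0.813953488372093
survival_medians:
  resection: 55.0
  ablation: 37.0
  tace: 18.0
  sorafenib: 9.0
censor_horizon_months: 84.0
missing_rate: ~
age_mean: 66.0
age_sd: 11.0
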