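method,group,sensitivity,specificity,n_pos,n_neg
junior,overall,77.24,79.54,123,347
senior,overall,82.93,84.15,123,347
cad,overall,84.55,83.29,123,347
junior_cad,overall,87.80,88.18,123,347
senior_cad,overall,88.62,89.04,123,347
cad,LuminalA,82.61,82.93,23,82
cad,LuminalB,81.58,80.71,38,140
cad,HER2+,86.20,84.72,29,72
cad,TN,87.88,88.68,33,53
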