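# Bundled demo configuration: small synthetic cohort, grid/trajectory off.
[global]
seed = 1

[synthetic]
use = TRUE
n_admissions = 500
frac_medical = 0.417
true_ate_vfd = -0.15
true_pf_effect = -2
mp_threshold_true = 17
max_hours = 30

[pipeline]
window_hours = 24
min_complete_hours = 2

[estimators]
estimators = backdoor_lr, dml_forest, dml_generic
cate_estimator = backdoor_lr
n_boot = 200
k_folds = 5
num_trees = 100
min_n = 50

[grid]
enabled = FALSE

[trajectory]
enabled = FALSE
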