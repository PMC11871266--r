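# Default ventilation causal graph.
# Clinical labs/vitals and demographics feed a latent disease-severity score;
# severity drives oxygenation (pf_ratio) and ventilator-free days, and
# clinicians titrate respiratory rate and peak pressure to severity. Those
# settings plus latent lung compliance determine mechanical power (exposure).
node age observed covariate
node admission_type observed covariate
node wbc observed covariate
node temperature observed covariate
node ph observed covariate
node map observed covariate
node paco2 observed covariate
node rr observed covariate
node peak_pressure observed covariate
node compliance unobserved covariate
node disease_score unobserved covariate
node mechanical_power observed exposure
node pf_ratio observed intermediary
node vent_free_days observed outcome
age -> disease_score
admission_type -> disease_score
wbc -> disease_score
temperature -> disease_score
ph -> disease_score
map -> disease_score
paco2 -> disease_score
disease_score -> rr
disease_score -> peak_pressure
disease_score -> pf_ratio
rr -> mechanical_power
peak_pressure -> mechanical_power
compliance -> mechanical_power
mechanical_power -> pf_ratio
mechanical_power -> vent_free_days
pf_ratio -> vent_free_days
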