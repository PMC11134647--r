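# Default sex-stratified sleep-mediation model.
# Latent obesity is measured by BMI, waist circumference and body fat mass
# (reference indicator: bmi, loading fixed to 1). Sleep duration mediates
# the effect of every exogenous predictor on continuous MetS severity.
# Exogenous variables covary freely (added automatically by parse_model).

obesity =~ bmi + wc + bfm

sleep_duration ~ age + ses + physical_activity + obesity + sleep_latency + nap_duration + night_shift

mets_severity ~ age + ses + physical_activity + obesity + sleep_latency + nap_duration + night_shift + sleep_duration
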