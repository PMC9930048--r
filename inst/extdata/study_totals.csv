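group,total_deaths,period_years
adult mortality COPD/IHD/LC/stroke,3609,9
ALRI mortality children 0-4,298,9
post-neonatal infant mortality,2739,9
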