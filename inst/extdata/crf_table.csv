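endpoint,pollutant,rr_central,rr_low,rr_high,cutoff,form
respiratory mortality,PM2.5,1.0051,1.0030,1.0073,5,log_linear
respiratory mortality,PM10,1.0032,1.0023,1.0040,15,log_linear
cardiovascular mortality,PM2.5,1.0044,1.0033,1.0054,5,log_linear
cardiovascular mortality,PM10,1.0043,1.0037,1.0049,15,log_linear
lung cancer mortality,PM2.5,1.11,1.05,1.18,5,log_linear
respiratory hospital admissions,PM10,1.008,1.0048,1.0112,15,log_linear
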