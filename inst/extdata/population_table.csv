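zone,count,representativeness,zone_share_source
coastal,396252,0.581,synthetic
industrial,264168,0.693,synthetic
mountainous,220140,0.638,synthetic
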