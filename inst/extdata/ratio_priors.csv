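zone,month,ratio,sd,n,source
industrial,all,0.5,0.3,0,prior
coastal,all,0.4,0.2,0,prior
mountainous,all,0.4,0.2,0,prior
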