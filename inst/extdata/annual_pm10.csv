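zone,year,mean,sd
coastal,2011,22,10
coastal,2012,28,17
coastal,2013,26,14
coastal,2014,30,14
coastal,2015,33,18
coastal,2016,26,12
coastal,2017,28,16
coastal,2018,32,17
coastal,2019,26,10
industrial,2011,37,15
industrial,2012,39,14
industrial,2013,43,30
industrial,2014,39,13
industrial,2015,44,14
industrial,2016,38,13
industrial,2017,39,14
industrial,2018,37,12
industrial,2019,36,10
mountainous,2011,27,15
mountainous,2012,29,14
mountainous,2013,29,15
mountainous,2014,38,15
mountainous,2015,36,13
mountainous,2016,57,14
mountainous,2017,35,19
mountainous,2018,35,14
mountainous,2019,33,14
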