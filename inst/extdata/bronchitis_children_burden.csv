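endpoint,year,zone,ap_pct,cases
bronchitis prevalence children 0-4,2011,region,8.0,41
bronchitis prevalence children 0-4,2011,coastal,5.0,12
bronchitis prevalence children 0-4,2011,industrial,15.7,13
bronchitis prevalence children 0-4,2011,mountainous,8.6,16
bronchitis prevalence children 0-4,2012,region,13.0,80
bronchitis prevalence children 0-4,2012,coastal,12.8,47
bronchitis prevalence children 0-4,2012,industrial,17.5,18
bronchitis prevalence children 0-4,2012,mountainous,10.3,15
bronchitis prevalence children 0-4,2013,region,12.9,91
bronchitis prevalence children 0-4,2013,coastal,11.6,40
bronchitis prevalence children 0-4,2013,industrial,19.2,30
bronchitis prevalence children 0-4,2013,mountainous,10.4,21
bronchitis prevalence children 0-4,2014,region,14.8,136
bronchitis prevalence children 0-4,2014,coastal,14.0,77
bronchitis prevalence children 0-4,2014,industrial,16.6,26
bronchitis prevalence children 0-4,2014,mountainous,15.8,33
bronchitis prevalence children 0-4,2015,region,15.0,155
bronchitis prevalence children 0-4,2015,coastal,12.9,71
bronchitis prevalence children 0-4,2015,industrial,19.1,53
bronchitis prevalence children 0-4,2015,mountainous,14.9,31
bronchitis prevalence children 0-4,2016,region,13.1,100
bronchitis prevalence children 0-4,2016,coastal,7.8,32
bronchitis prevalence children 0-4,2016,industrial,16.2,41
bronchitis prevalence children 0-4,2016,mountainous,27.3,27
bronchitis prevalence children 0-4,2017,region,11.5,105
bronchitis prevalence children 0-4,2017,coastal,9.6,61
bronchitis prevalence children 0-4,2017,industrial,16.5,29
bronchitis prevalence children 0-4,2017,mountainous,14.9,15
bronchitis prevalence children 0-4,2018,region,13.4,122
bronchitis prevalence children 0-4,2018,coastal,12.2,70
bronchitis prevalence children 0-4,2018,industrial,15.6,37
bronchitis prevalence children 0-4,2018,mountainous,15.0,15
bronchitis prevalence children 0-4,2019,region,9.6,199
bronchitis prevalence children 0-4,2019,coastal,7.9,119
bronchitis prevalence children 0-4,2019,industrial,15.1,58
bronchitis prevalence children 0-4,2019,mountainous,12.8,22
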