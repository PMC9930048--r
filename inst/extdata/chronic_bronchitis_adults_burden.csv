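endpoint,year,zone,ap_pct,cases
chronic bronchitis incidence adults,2011,region,11.3,90
chronic bronchitis incidence adults,2011,coastal,7.3,33
chronic bronchitis incidence adults,2011,industrial,21.7,33
chronic bronchitis incidence adults,2011,mountainous,12.5,24
chronic bronchitis incidence adults,2012,region,14.7,123
chronic bronchitis incidence adults,2012,coastal,13.3,70
chronic bronchitis incidence adults,2012,industrial,23.1,25
chronic bronchitis incidence adults,2012,mountainous,13.9,28
chronic bronchitis incidence adults,2013,region,14.7,139
chronic bronchitis incidence adults,2013,coastal,11.4,68
chronic bronchitis incidence adults,2013,industrial,26.1,46
chronic bronchitis incidence adults,2013,mountainous,14.5,25
chronic bronchitis incidence adults,2014,region,17.7,198
chronic bronchitis incidence adults,2014,coastal,14.8,105
chronic bronchitis incidence adults,2014,industrial,23.3,37
chronic bronchitis incidence adults,2014,mountainous,22.3,56
chronic bronchitis incidence adults,2015,region,20.5,244
chronic bronchitis incidence adults,2015,coastal,18.0,111
chronic bronchitis incidence adults,2015,industrial,26.4,61
chronic bronchitis incidence adults,2015,mountainous,21.1,72
chronic bronchitis incidence adults,2016,region,17.6,218
chronic bronchitis incidence adults,2016,coastal,11.0,87
chronic bronchitis incidence adults,2016,industrial,22.3,56
chronic bronchitis incidence adults,2016,mountainous,37.1,75
chronic bronchitis incidence adults,2017,region,11.4,165
chronic bronchitis incidence adults,2017,coastal,9.6,94
chronic bronchitis incidence adults,2017,industrial,16.5,40
chronic bronchitis incidence adults,2017,mountainous,14.3,31
chronic bronchitis incidence adults,2018,region,18.3,307
chronic bronchitis incidence adults,2018,coastal,17.0,190
chronic bronchitis incidence adults,2018,industrial,21.6,62
chronic bronchitis incidence adults,2018,mountainous,20.1,55
chronic bronchitis incidence adults,2019,region,13.9,383
chronic bronchitis incidence adults,2019,coastal,11.2,206
chronic bronchitis incidence adults,2019,industrial,20.7,96
chronic bronchitis incidence adults,2019,mountainous,18.2,81
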