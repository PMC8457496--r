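country,year,station,sampling_date,n_fish,sl_min,sl_max,n_otoliths,n_larval_ring_otoliths,latitude,longitude,survey,overwinter
BE,2013,BEW1,2013-08-28,40,70.9,104.3,20,4,51.23,2.80,B-FishConnect,FALSE
BE,2013,BEW2,2013-09-10,39,59.3,110.3,15,2,51.19,2.70,DYFS,FALSE
BE,2013,BEE1,2013-09-09,37,74.7,104.7,7,3,51.35,3.00,DYFS,FALSE
BE,2014,BEW1,2014-05-26,79,93.3,144.6,7,NA,51.23,2.80,B-FishConnect,TRUE
BE,2014,BEW3,2014-09-15,33,64.7,95.4,16,3,51.13,2.70,DYFS,FALSE
BE,2014,BEE1,2014-09-16,28,72.7,101.41,8,2,51.35,3.00,DYFS,FALSE
BE,2014,BEE2,2014-10-10,33,74.7,106.9,17,4,51.35,3.10,B-FishConnect,FALSE
NL,2014,NL1,2014-09-16,39,72.4,101.5,16,4,53.48,6.49,DYFS,FALSE
NL,2014,NL2,2014-09-23,30,75.9,108.4,21,3,53.35,6.97,DYFS,FALSE
UK,2016,UK1,2016-03-14,21,53.4,87.5,19,3,52.21,1.63,Cefas,TRUE
UK,2016,UK2,2016-03-04,23,53.9,78.6,8,3,52.21,1.63,Cefas,TRUE
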