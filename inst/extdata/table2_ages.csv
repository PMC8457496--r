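station,year,age_mean,age_sd,pld_mean,pld_sd,settlement_date,hatching_date,overwinter
BEW1,2013,120,16,31.19,1.77,2013-05-31,2013-04-29,FALSE
BEW2,2013,137,12,35.89,2.72,2013-05-31,2013-04-26,FALSE
BEE1,2013,148,13,38.67,2.34,2013-05-22,2013-04-13,FALSE
BEW1,2014,316,11,35.50,2.12,NA,NA,TRUE
BEW3,2014,138,7,34.27,1.81,2014-06-03,2014-04-30,FALSE
BEE1,2014,147,14,32.50,4.18,2014-05-24,2014-04-21,FALSE
BEE2,2014,140,20,38.94,2.87,2014-06-30,2014-05-22,FALSE
NL1,2014,141,15,32.50,2.15,2014-05-30,2014-04-28,FALSE
NL2,2014,149,17,32.71,3.69,2014-05-30,2014-04-27,FALSE
UK1,2016,NA,NA,33.76,3.80,NA,NA,TRUE
UK2,2016,NA,NA,33.81,2.34,NA,NA,TRUE
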