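station,year,age_mean,age_sd,sl_mean,sl_sd,or_mean,or_sd,pld_size_mean,pld_size_sd,growth_mean,growth_sd,sst_mean,sst_sd,overwinter
BEW1,2013,120,16,82.86,13.81,0.833,0.099,0.206,0.026,0.649,0.083,11.38,0.18,FALSE
BEW2,2013,137,12,83.92,7.33,0.925,0.107,0.210,0.034,0.619,0.082,11.38,0.18,FALSE
BEE1,2013,148,13,78.32,6.55,0.864,0.074,0.197,0.015,0.554,0.035,11.38,0.18,FALSE
BEW1,2014,316,11,106.37,9.86,1.164,0.151,NA,NA,NA,NA,NA,NA,TRUE
BEW3,2014,138,7,76.41,6.13,0.905,0.097,0.203,0.026,0.544,0.064,16.78,1.78,FALSE
BEE1,2014,147,14,78.85,6.66,0.976,0.093,0.202,0.031,0.547,0.033,16.78,1.78,FALSE
BEE2,2014,140,20,82.17,6.81,0.961,0.093,0.216,0.022,0.590,0.102,16.78,1.78,FALSE
NL1,2014,141,15,77.34,6.35,0.948,0.055,0.216,0.022,0.552,0.067,17.38,1.28,FALSE
NL2,2014,149,17,81.58,7.27,0.936,0.079,0.208,0.031,0.528,0.072,17.38,1.28,FALSE
UK1,2016,NA,NA,69.55,9.88,0.909,0.121,0.207,0.030,NA,NA,NA,NA,TRUE
UK2,2016,NA,NA,66.90,6.72,0.851,0.064,0.194,0.045,NA,NA,NA,NA,TRUE
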