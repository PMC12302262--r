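database,variable,category,n,printed_pct,is_missing
pei,sex,female,694572,71.98,FALSE
pei,sex,male,270362,28.02,FALSE
pei,sex,missing,9997,1.03,TRUE
pei,age_group,under2,66,0.01,FALSE
pei,age_group,2to6,801,0.09,FALSE
pei,age_group,7to17,16129,1.72,FALSE
pei,age_group,18to59,773889,82.59,FALSE
pei,age_group,over59,146154,15.6,FALSE
pei,age_group,missing,37892,3.89,TRUE
pei,vaccine_type,mrna,745174,76.88,FALSE
pei,vaccine_type,viral_vector,220371,22.74,FALSE
pei,vaccine_type,protein_subunit,3658,0.38,FALSE
pei,vaccine_type,inactivated,18,NA,FALSE
pei,vaccine_type,missing,5710,0.59,TRUE
pei,schedule,primer,962881,99.35,FALSE
pei,schedule,booster,6340,0.65,FALSE
pei,schedule,missing,5710,0.59,TRUE
pei,year,2020,113,0.01,FALSE
pei,year,2021,601610,61.71,FALSE
pei,year,2022,317453,32.56,FALSE
pei,year,2023,55755,5.72,FALSE
vaers,sex,female,647009,66.50,FALSE
vaers,sex,male,325929,33.50,FALSE
vaers,sex,missing,43086,4.24,TRUE
vaers,age_group,under2,2807,0.31,FALSE
vaers,age_group,2to6,8917,0.98,FALSE
vaers,age_group,7to17,51139,5.61,FALSE
vaers,age_group,18to59,516801,56.65,FALSE
vaers,age_group,over59,332564,36.46,FALSE
vaers,age_group,missing,103796,10.22,TRUE
vaers,vaccine_type,mrna,939716,92.73,FALSE
vaers,vaccine_type,viral_vector,73201,7.22,FALSE
vaers,vaccine_type,protein_subunit,511,0.05,FALSE
vaers,vaccine_type,missing,2596,0.26,TRUE
vaers,schedule,primer,972752,95.99,FALSE
vaers,schedule,booster,40676,4.01,FALSE
vaers,schedule,missing,2596,0.26,TRUE
vaers,year,2020,10380,1.02,FALSE
vaers,year,2021,710616,69.94,FALSE
vaers,year,2022,210534,20.72,FALSE
vaers,year,2023,71074,7.00,FALSE
vaers,year,2024,13420,1.32,FALSE
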