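patient_id,age,sex,weight_day6,dose_day6,c0_day6,weight_month6,dose_month6,c0_month6,weight_year1,dose_year1,c0_year1,nodat,rejection,toxicity,erythrocytosis,dgf,early_dysfunction,rs776746,rs2242480,rs2740574,rs2032582,rs1045642
P0001,31.014,male,57.736,3.715,8.291,,,,88.048,6.718,11.274,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,*1/*3,*1/*1G,A/A,T/T,C/T
P0002,38.37,female,61.695,3.267,5.236,81.518,4.526,4.468,,,,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,*3/*3,*1/*1,A/A,G/T,T/T
P0003,33.915,male,57.002,4.222,12.578,,,,66.595,3.693,11.348,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,*3/*3,*1/*1,A/A,G/T,C/C
P0004,40.131,female,55.817,4.008,2.84,75.323,4.226,7.619,,,,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,*1/*3,*1/*1G,A/A,G/T,C/T
P0005,38.54,male,37.315,2.421,17.013,40.03,2.469,2.89,41.356,2.851,7.267,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,*3/*3,*1/*1,A/A,T/T,C/C
P0006,48.931,male,56.054,4.121,7.611,,,,69.636,5.3,10.872,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,*1/*3,*1/*1G,A/A,G/G,C/C
P0007,42.889,female,36.475,2.068,3.624,50.918,3.889,3.682,56.659,4.161,12.364,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,*1/*3,*1/*1G,A/G,G/T,C/T
P0008,27.175,male,74.328,4.989,12.662,56.812,4.071,6.084,61.511,4.267,13.932,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,*3/*3,*1/*1,A/A,G/T,C/T
P0009,42.717,male,46.687,3.567,6.258,49.428,3.938,4.28,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,*3/*3,*1/*1,A/A,T/T,C/T
P0010,27.882,male,61.45,4.806,17.864,67.627,3.527,3.88,76.867,5.012,12.145,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,*3/*3,*1/*1,,T/T,T/T
P0011,24.366,male,66.21,5.281,6.533,,,,63.038,3.264,11.957,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,*3/*3,*1/*1,A/A,G/G,C/C
P0012,44.841,male,59.62,3.92,3.934,56.767,4.358,15.557,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,*3/*3,*1/*1,A/A,T/T,T/T
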