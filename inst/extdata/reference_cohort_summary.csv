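cluster,n,outcome,type,mean,count,denom
1,304,age_years,continuous,59.7,NA,NA
2,191,age_years,continuous,63.2,NA,NA
3,229,age_years,continuous,61.4,NA,NA
4,144,age_years,continuous,61.1,NA,NA
5,123,age_years,continuous,61.9,NA,NA
1,304,apache_ii,continuous,13.5,NA,NA
2,191,apache_ii,continuous,15.7,NA,NA
3,229,apache_ii,continuous,14.6,NA,NA
4,144,apache_ii,continuous,13.3,NA,NA
5,123,apache_ii,continuous,14.7,NA,NA
1,304,mrc_icu,continuous,9.4,NA,NA
2,191,mrc_icu,continuous,11.6,NA,NA
3,229,mrc_icu,continuous,10.0,NA,NA
4,144,mrc_icu,continuous,10.1,NA,NA
5,123,mrc_icu,continuous,11.2,NA,NA
1,304,vasopressor_days,continuous,2.1,NA,NA
2,191,vasopressor_days,continuous,1.4,NA,NA
3,229,vasopressor_days,continuous,1.5,NA,NA
4,144,vasopressor_days,continuous,2.1,NA,NA
5,123,vasopressor_days,continuous,1.2,NA,NA
1,304,mortality,categorical,NA,30,304
2,191,mortality,categorical,NA,11,191
3,229,mortality,categorical,NA,27,229
4,144,mortality,categorical,NA,19,144
5,123,mortality,categorical,NA,10,123
1,304,female,categorical,NA,136,304
2,191,female,categorical,NA,80,191
3,229,female,categorical,NA,96,229
4,144,female,categorical,NA,69,144
5,123,female,categorical,NA,47,123
1,304,medical_icu,categorical,NA,111,304
2,191,medical_icu,categorical,NA,70,191
3,229,medical_icu,categorical,NA,104,229
4,144,medical_icu,categorical,NA,54,144
5,123,medical_icu,categorical,NA,65,123
1,304,mech_ventilation,categorical,NA,91,304
2,191,mech_ventilation,categorical,NA,83,191
3,229,mech_ventilation,categorical,NA,60,229
4,144,mech_ventilation,categorical,NA,37,144
5,123,mech_ventilation,categorical,NA,41,123
1,304,aki,categorical,NA,52,303
2,191,aki,categorical,NA,22,191
3,229,aki,categorical,NA,40,229
4,144,aki,categorical,NA,26,144
5,123,aki,categorical,NA,14,122
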