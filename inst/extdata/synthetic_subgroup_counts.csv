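cell,sex,birth_date,n,n_mltc,n_pm
male_under_45,male,1990-01-01,2800,2000,900
male_ge_45,male,1960-01-01,4030,3757,1155
female_under_45,female,1990-01-01,2706,2350,900
female_ge_45,female,1960-01-01,3533,3124,1207
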