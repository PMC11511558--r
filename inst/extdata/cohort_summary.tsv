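variable	type	hd_count	hc_count	hd_mean	hd_sd	hc_mean	hc_sd
Male	count	7	7	NA	NA	NA	NA
Female	count	5	12	NA	NA	NA	NA
Age	continuous	NA	NA	59	12	46	16
Black/African American	count	7	2	NA	NA	NA	NA
Asian/Pacific Islander	count	1	2	NA	NA	NA	NA
White/Caucasian	count	2	10	NA	NA	NA	NA
Hispanic/Latinx	count	2	5	NA	NA	NA	NA
BMI	continuous	NA	NA	25	8	29	8
Diabetes	count	7	2	NA	NA	NA	NA
Hypertension	count	8	3	NA	NA	NA	NA
Positive COVID-19	count	6	4	NA	NA	NA	NA
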