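study	sex	region	model	beta	lcl	ucl
CKB	all	both	observational	0.033	0.027	0.039
CKB	male	both	observational	0.047	0.038	0.056
CKB	female	both	observational	0.024	0.017	0.032
CKB	all	urban	observational	0.020	0.011	0.030
CKB	male	urban	observational	0.030	0.015	0.044
CKB	female	urban	observational	0.016	0.004	0.028
CKB	all	rural	observational	0.034	0.027	0.041
CKB	male	rural	observational	0.051	0.040	0.063
CKB	female	rural	observational	0.025	0.015	0.034
CKB	all	both	genetic	0.026	-0.007	0.059
CKB	male	both	genetic	-0.006	-0.064	0.052
CKB	female	both	genetic	0.041	0.002	0.081
CKB	all	urban	genetic	0.022	-0.031	0.076
CKB	male	urban	genetic	-0.004	-0.100	0.091
CKB	female	urban	genetic	0.035	-0.030	0.099
CKB	all	rural	genetic	0.028	-0.013	0.070
CKB	male	rural	genetic	-0.008	-0.080	0.065
CKB	female	rural	genetic	0.045	-0.005	0.095
UKB	all	both	observational	-0.179	-0.181	-0.177
UKB	male	both	observational	-0.181	-0.185	-0.178
UKB	female	both	observational	-0.182	-0.185	-0.179
UKB	all	urban	observational	-0.178	-0.181	-0.176
UKB	male	urban	observational	-0.180	-0.184	-0.176
UKB	female	urban	observational	-0.181	-0.184	-0.178
UKB	all	rural	observational	-0.179	-0.185	-0.173
UKB	male	rural	observational	-0.185	-0.194	-0.176
UKB	female	rural	observational	-0.178	-0.185	-0.170
UKB	all	both	genetic	-0.183	-0.200	-0.165
UKB	male	both	genetic	-0.231	-0.254	-0.208
UKB	female	both	genetic	-0.206	-0.229	-0.184
UKB	all	urban	genetic	-0.184	-0.202	-0.165
UKB	male	urban	genetic	-0.234	-0.260	-0.209
UKB	female	urban	genetic	-0.203	-0.228	-0.179
UKB	all	rural	genetic	-0.167	-0.213	-0.122
UKB	male	rural	genetic	-0.173	-0.234	-0.113
UKB	female	rural	genetic	-0.177	-0.241	-0.114
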