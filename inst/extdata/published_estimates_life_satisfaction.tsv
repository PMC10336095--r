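study	sex	region	model	beta	lcl	ucl
CKB	all	both	observational	0.058	0.053	0.063
CKB	male	both	observational	0.054	0.047	0.062
CKB	female	both	observational	0.062	0.056	0.069
CKB	all	urban	observational	0.048	0.041	0.055
CKB	male	urban	observational	0.059	0.048	0.070
CKB	female	urban	observational	0.043	0.034	0.052
CKB	all	rural	observational	0.066	0.059	0.072
CKB	male	rural	observational	0.072	0.062	0.081
CKB	female	rural	observational	0.063	0.055	0.072
CKB	all	both	genetic	-0.028	-0.055	-0.002
CKB	male	both	genetic	-0.077	-0.123	-0.030
CKB	female	both	genetic	-0.004	-0.037	0.028
CKB	all	urban	genetic	0.006	-0.036	0.048
CKB	male	urban	genetic	-0.033	-0.109	0.042
CKB	female	urban	genetic	0.024	-0.027	0.075
CKB	all	rural	genetic	-0.051	-0.085	-0.016
CKB	male	rural	genetic	-0.103	-0.162	-0.044
CKB	female	rural	genetic	-0.023	-0.066	0.019
UKB	all	both	observational	-0.019	-0.023	-0.014
UKB	male	both	observational	-0.002	-0.008	0.005
UKB	female	both	observational	-0.029	-0.035	-0.023
UKB	all	urban	observational	-0.020	-0.025	-0.015
UKB	male	urban	observational	-0.005	-0.013	0.002
UKB	female	urban	observational	-0.028	-0.035	-0.022
UKB	all	rural	observational	-0.013	-0.024	-0.002
UKB	male	rural	observational	0.015	-0.002	0.032
UKB	female	rural	observational	-0.030	-0.045	-0.015
UKB	all	both	genetic	-0.019	-0.054	0.016
UKB	male	both	genetic	-0.003	-0.049	0.043
UKB	female	both	genetic	-0.030	-0.073	0.014
UKB	all	urban	genetic	-0.027	-0.066	0.011
UKB	male	urban	genetic	-0.003	-0.054	0.048
UKB	female	urban	genetic	-0.031	-0.079	0.016
UKB	all	rural	genetic	0.030	-0.058	0.119
UKB	male	rural	genetic	0.026	-0.085	0.137
UKB	female	rural	genetic	0.010	-0.111	0.130
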