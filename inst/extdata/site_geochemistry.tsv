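site_id	water_depth_km	TSF_max	UCM_ug_g	sum_n_alkanes_ng_g	TD_ratio	total_alkane_gas_ppm	c2plus_ppm	c1_c2c3_ratio	d13C_CH4_permil
E26	2.8	57326.7	32	2845.3	1.0	9	0.3	NA	NA
E29	3.2	26738.3	13	2527	2.6	936012	17.5	3974.2	-85.1
E44	3.0	13502.3	7.3	1045	0.8	9.9	0.5	NA	NA
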