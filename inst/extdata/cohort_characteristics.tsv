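characteristic	value
n_total	10893
n_female	5784
pct_never	18.10
pct_former	17.00
pct_infrequent	21.80
pct_low_to_moderate	34.36
pct_heavy	8.75
mean_alcohol_g_wk	45.7
mean_tg_mg_dl	137.1
mean_total_chol_mg_dl	214.5
mean_hdl_mg_dl	50.5
mean_hdl3_mg_dl	36.8
mean_ldl_mg_dl	137.6
mean_sdldl_mg_dl	45.2
mean_apob_mg_dl	100.6
median_lpa_mg_dl	8.2
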