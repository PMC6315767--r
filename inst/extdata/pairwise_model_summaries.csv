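pair,r2x_cum,r2,q2,permutation_pass,p_cv_anova,r2_minus_q2_printed,valid_printed,significant_printed
PA vs HC,0.63,0.95,0.71,TRUE,1.83e-3,0.24,TRUE,TRUE
PA vs PB,0.60,0.88,0.51,TRUE,1.37e-1,0.37,FALSE,FALSE
PA vs PC,0.65,0.88,0.66,TRUE,1.00e-2,0.22,TRUE,TRUE
PA vs PD,0.67,0.89,0.43,TRUE,2.42e-1,0.46,FALSE,FALSE
PA vs PE,0.47,0.67,0.33,TRUE,1.56e-1,0.34,FALSE,FALSE
HC vs PB,0.68,0.99,0.91,TRUE,2.03e-6,0.08,TRUE,TRUE
HC vs PC,0.67,0.99,0.91,TRUE,4.81e-7,0.08,TRUE,TRUE
HC vs PD,0.72,0.99,0.86,TRUE,6.69e-4,0.13,TRUE,TRUE
HC vs PE,0.54,0.99,0.72,TRUE,1.19e-2,0.27,TRUE,TRUE
PB vs PC,0.68,0.97,0.08,TRUE,9.97e-1,0.89,FALSE,FALSE
PB vs PD,0.61,0.76,0.12,TRUE,7.16e-1,0.64,FALSE,FALSE
PB vs PE,0.63,0.99,0.93,TRUE,3.31e-7,0.06,TRUE,TRUE
PC vs PD,0.58,0.68,0.24,TRUE,2.98e-1,0.44,FALSE,FALSE
PC vs PE,0.60,0.98,0.89,TRUE,1.90e-7,0.09,TRUE,TRUE
PD vs PE,0.57,0.84,0.69,TRUE,3.43e-4,0.15,TRUE,TRUE
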