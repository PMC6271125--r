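name,compound,matrix,temp_c,W,F_pct,k1,rsd_k1,k2,rsd_k2,tau1,rsd_tau1,tau2,rsd_tau2,rmse
ethyl_hexanoate_30C,ethyl hexanoate,alcoholic beverage,30,5.95,13.48,3.11e9,2.41,3.10e9,2.36,13.34,4.33,13.50,4.37,0.17
hexyl_acetate_30C,hexyl acetate,alcoholic beverage,30,326.38,15.33,1.77e9,3.62,1.75e9,3.52,21.93,4.15,22.44,4.04,0.10
cis_3_hexenyl_acetate_30C,cis-3-hexenyl acetate,alcoholic beverage,30,199.50,7.16,4.06e9,3.54,4.04e9,3.56,22.00,0.00,22.09,0.05,0.08
allyl_hexanoate_30C,allyl hexanoate,alcoholic beverage,30,1.15,3.61,6.23e9,1.09,6.18e9,1.03,47.96,0.77,48.40,0.72,0.09
ethyl_octanoate_30C,ethyl octanoate,alcoholic beverage,30,304.83,8.89,6.93e9,2.36,6.85e9,2.26,106.94,2.39,108.82,1.87,0.06
isoamyl_hexanoate_30C,isoamyl hexanoate,alcoholic beverage,30,349.99,7.52,9.27e9,3.58,9.17e9,3.65,113.10,0.29,115.00,0.00,0.05
ethyl_hexanoate_40C,ethyl hexanoate,alcoholic beverage,40,3.53,2.55,2.58e9,0.36,2.57e9,0.35,13.63,0.87,13.80,0.98,0.19
hexyl_acetate_40C,hexyl acetate,alcoholic beverage,40,885.24,12.72,1.67e9,0.81,1.65e9,0.92,11.72,5.49,11.90,5.51,0.06
cis_3_hexenyl_acetate_40C,cis-3-hexenyl acetate,alcoholic beverage,40,28.86,10.69,8.30e8,3.11,8.18e8,3.28,14.17,1.99,14.37,2.30,0.12
allyl_hexanoate_40C,allyl hexanoate,alcoholic beverage,40,30.88,5.84,3.01e9,0.73,2.98e9,0.67,35.79,2.16,36.53,2.28,0.12
ethyl_octanoate_40C,ethyl octanoate,alcoholic beverage,40,227.48,5.94,8.71e9,2.55,8.66e9,2.52,58.30,0.46,59.08,0.41,0.11
isoamyl_hexanoate_40C,isoamyl hexanoate,alcoholic beverage,40,34.02,4.85,8.01e9,0.17,7.94e9,0.23,61.86,2.20,63.09,2.25,0.10
ethyl_decanoate_40C,ethyl decanoate,alcoholic beverage,40,863.01,16.56,2.25e10,3.56,2.23e10,3.72,322.53,4.71,326.39,4.57,0.04
allyl_hexanoate_60C,allyl hexanoate,alcoholic beverage,60,748.05,4.69,1.38e9,2.36,1.36e9,2.31,9.10,0.00,9.26,0.02,0.07
ethyl_octanoate_60C,ethyl octanoate,alcoholic beverage,60,2.00,7.74,2.67e9,1.16,2.64e9,1.18,19.82,2.58,20.26,2.81,0.09
isoamyl_hexanoate_60C,isoamyl hexanoate,alcoholic beverage,60,2.81,6.55,3.51e9,1.34,3.47e9,1.37,20.27,1.82,20.77,2.02,0.08
ethyl_decanoate_60C,ethyl decanoate,alcoholic beverage,60,241.21,13.48,8.10e9,4.85,8.02e9,4.82,73.81,1.90,75.34,1.90,0.04
ethyl_lauroate_60C,ethyl lauroate,alcoholic beverage,60,642.31,13.42,6.10e10,2.21,6.08e10,2.28,358.69,4.51,360.80,4.42,0.06
sugar_free_ethyl_butanoate_60C,sugar-free ethyl butanoate,chewing gum,60,37.94,3.28,1.34e10,1.05,1.33e10,0.99,6.17,0.67,6.23,0.56,0.09
sugar_base_ethyl_butanoate_60C,sugar-base ethyl butanoate,chewing gum,60,1.01,5.10,3.68e9,2.18,3.63e9,2.06,2.49,0.27,2.51,0.58,0.04
sugar_free_ethyl_hexanoate_60C,sugar-free ethyl hexanoate,chewing gum,60,8.51,2.88,2.81e10,0.26,2.77e10,0.34,9.71,1.11,9.84,1.17,0.10
sugar_base_ethyl_hexanoate_60C,sugar-base ethyl hexanoate,chewing gum,60,11.38,8.31,2.18e10,0.57,2.16e10,0.58,4.29,3.57,4.32,3.58,0.07
sugar_free_isopentyl_acetate_60C,sugar-free isopentyl acetate,chewing gum,60,13.00,5.68,3.40e9,0.37,3.36e9,0.38,6.11,2.28,6.28,2.65,0.13
sugar_base_isopentyl_acetate_60C,sugar-base isopentyl acetate,chewing gum,60,81.08,13.33,1.86e9,2.28,1.85e9,2.34,2.05,4.36,2.10,4.34,0.08
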