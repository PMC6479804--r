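record,method,snr_imp,mse,prd
101,emd_wavelet,9.5,0.015,33.48
103,emd_wavelet,7.16,0.029,43.87
104,emd_wavelet,8.85,0.016,36.09
105,emd_wavelet,9.71,0.015,32.71
106,emd_wavelet,6.79,0.041,45.73
115,emd_wavelet,8.06,0.051,39.55
117,emd_wavelet,13.85,0.031,20.28
101,nlm,9.05,0.017,35.29
103,nlm,7.83,0.026,40.61
104,nlm,7.79,0.021,40.88
105,nlm,8.22,0.022,38.83
106,nlm,6.16,0.048,49.23
115,nlm,7.29,0.061,43.16
117,nlm,11.24,0.056,27.41
101,ldasg,10.47,0.012,29.96
103,ldasg,10.35,0.014,30.37
104,ldasg,10.39,0.011,30.21
105,ldasg,10.78,0.011,28.91
106,ldasg,9.45,0.022,33.69
115,ldasg,9.17,0.039,34.78
117,ldasg,14.91,0.024,17.98
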