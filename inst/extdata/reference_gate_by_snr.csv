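snr_db,g_ecg_mean,g_ecg_sd,g_acc_mean,g_acc_sd
24,0.73,0.35,0.39,0.38
12,0.71,0.36,0.41,0.39
6,0.69,0.37,0.43,0.40
0,0.68,0.38,0.45,0.41
-6,0.66,0.39,0.47,0.42
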