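category,activity,fp_ecg_only_pct,fp_fusion_pct,reduction_pct,accel_mag_g,f_dom_hz
Sedentary,Baseline,2.3,0.9,61,0.02,0.5
Sedentary,Greetings,3.7,1.2,68,0.05,0.8
Upper body,Gesticulate,8.2,2.8,66,0.15,2.5
Locomotion,Walk-Before,13.5,4.8,64,0.25,1.8
Locomotion,Walk-After,19.8,6.1,69,0.35,2.2
Vigorous,Run,36.2,10.4,71,0.85,2.8
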