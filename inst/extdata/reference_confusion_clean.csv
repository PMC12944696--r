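true,pred_normal,pred_arrhythmia
Normal,8772,8
Arrhythmia,32,4182
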