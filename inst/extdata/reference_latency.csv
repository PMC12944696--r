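platform,t_stage1_ms,t_stage2_ms
RTX 3080 GPU,4.2,4.8
Raspberry Pi 4,156,178
STM32H7 (INT8),892,1024
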