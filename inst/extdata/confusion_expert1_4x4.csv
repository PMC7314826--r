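model,expert_A,expert_B,expert_C,expert_D
model_A,7,0,0,2
model_B,1,6,3,1
model_C,0,3,5,2
model_D,1,1,2,6
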