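model,expert_A,expert_B,expert_C,expert_D
model_A,5,2,1,1
model_B,2,9,0,0
model_C,1,5,1,3
model_D,1,3,3,3
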