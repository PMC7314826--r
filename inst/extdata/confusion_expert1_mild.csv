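model,expert_mild,expert_non_mild
model_mild,6,5
model_non_mild,4,25
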