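model,expert_severe,expert_non_severe
model_severe,5,4
model_non_severe,4,27
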