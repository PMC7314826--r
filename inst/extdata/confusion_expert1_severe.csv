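model,expert_severe,expert_non_severe
model_severe,7,2
model_non_severe,2,29
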