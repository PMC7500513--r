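{"space_length":600,"object_length":4,"shadow_offset":150,"shadow_sign":1,"trial_duration":60,"tick":0.01,"static_positions":[100,400]}
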