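id	arm5p_start	arm5p_end	arm3p_start	arm3p_end
pri-let-7a-1	36	57	87	107
pri-miR-26b	42	62	77	98
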