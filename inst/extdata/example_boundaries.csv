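"r_o_um","r_n_um"
280,103.2
340,176.9
420,265.1
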