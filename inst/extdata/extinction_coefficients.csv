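lambda_nm,alpha_hbo,alpha_hbr
640,0.0010177,0.0100052
660,0.0007359,0.0074295
690,0.0006355,0.0047248
760,0.0013493,0.0035656
830,0.0022427,0.0015958
850,0.0024361,0.0015918
910,0.0028874,0.0016727
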