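home_1.soil.wp00.r1
home_1.soil.wp00.r2
home_1.soil.wp04.r1
home_1.soil.wp04.r2
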