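freq_class	del_hh	neu_hh	del_out	neu_out
rare	650	1013	5469	9109
intermediate	470	1050	4241	10376
common	329	1206	2935	11710
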