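target	del_within	neu_within	del_flank	neu_flank
LCT	1	2	4	6
SLC45A2	1	0	3	8
TYRP1	0	0	1	3
OCA2-HERC2	3	2	3	2
KITLG	0	0	1	5
SLC24A5	1	0	2	3
TYR	2	0	6	1
EDAR	1	1	2	5
PCDH15	0	0	0	0
LEPR	2	1	2	2
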