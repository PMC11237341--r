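name	length_bs	spacer_bs	length_bt	spacer_bt
tRNA-Phe	70	0	71	0
12S	925	-4	925	-4
tRNA-Val	70	3	71	14
16S	1594	-2	1594	-2
tRNA-Leu2	75	0	74	0
ND1	974	3	974	3
tRNA-Ile	71	-1	71	-1
tRNA-Gln	72	-1	72	-1
tRNA-Met	69	0	69	0
ND2	1041	-2	1041	-2
tRNA-Trp	69	0	69	0
tRNA-Ala	69	0	69	0
tRNA-Asn	73	2	73	2
OL	28	-1	30	-1
tRNA-Cys	63	0	63	0
tRNA-Tyr	67	1	67	1
COI	1557	-5	1563	-10
tRNA-Ser2	71	3	71	3
tRNA-Asp	67	0	68	0
COII	685	0	685	0
tRNA-Lys	73	1	73	1
ATP8	165	-10	165	-10
ATP6	683	-1	683	-1
COIII	785	-1	785	-1
tRNA-Gly	69	0	69	0
ND3	345	-2	345	-2
tRNA-Arg	69	3	69	3
ND4L	297	-7	297	-7
ND4	1378	6	1381	0
tRNA-His	69	6	69	0
tRNA-Ser1	62	0	67	0
tRNA-Leu1	73	0	73	0
ND5	1818	7	1818	3
ND6	510	0	510	0
tRNA-Glu	69	2	69	2
Cytb	1140	-1	1140	-1
tRNA-Thr	71	0	70	1
tRNA-Pro	69	0	69	-1
D-loop	1496	0	1380	0
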