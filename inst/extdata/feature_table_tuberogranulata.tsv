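name	type	start	end	strand	start_codon	stop_codon	anticodon
tRNA-Phe	tRNA	1	71	H			GAA
12S	rRNA	72	996	H			
tRNA-Val	tRNA	993	1063	H			TAC
16S	rRNA	1078	2671	H			
tRNA-Leu2	tRNA	2670	2743	H			TAA
ND1	PCG	2744	3717	H	ATG	TA(A)	
tRNA-Ile	tRNA	3721	3791	H			GAT
tRNA-Gln	tRNA	3791	3862	L			TTG
tRNA-Met	tRNA	3862	3930	H			CAT
ND2	PCG	3931	4971	H	ATT	TAG	
tRNA-Trp	tRNA	4970	5038	H			TCA
tRNA-Ala	tRNA	5039	5107	L			TGC
tRNA-Asn	tRNA	5108	5180	L			GTT
OL	origin	5183	5212	H			
tRNA-Cys	tRNA	5212	5274	L			GCA
tRNA-Tyr	tRNA	5275	5341	L			GTA
COI	PCG	5343	6905	H	GTG	AGA	
tRNA-Ser2	tRNA	6896	6966	L			TGA
tRNA-Asp	tRNA	6970	7037	H			GTC
COII	PCG	7038	7722	H	ATG	T(AA)	
tRNA-Lys	tRNA	7723	7795	H			TTT
ATP8	PCG	7797	7961	H	ATG	TAA	
ATP6	PCG	7952	8634	H	ATG	TA(A)	
COIII	PCG	8634	9418	H	ATG	TA(A)	
tRNA-Gly	tRNA	9418	9486	H			TCC
ND3	PCG	9487	9831	H	ATG	TAG	
tRNA-Arg	tRNA	9830	9898	H			TCG
ND4L	PCG	9902	10198	H	ATG	TAA	
ND4	PCG	10192	11572	H	ATG	T(AA)	
tRNA-His	tRNA	11573	11641	H			GTG
tRNA-Ser1	tRNA	11642	11708	H			GCT
tRNA-Leu1	tRNA	11709	11781	H			TAG
ND5	PCG	11782	13599	H	ATG	TAA	
ND6	PCG	13603	14112	L	ATG	AGA	
tRNA-Glu	tRNA	14113	14181	L			TTC
Cytb	PCG	14184	15323	H	ATG	TAG	
tRNA-Thr	tRNA	15323	15392	H			TGT
tRNA-Pro	tRNA	15394	15462	L			TGG
D-loop	control	15462	16841	H			
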