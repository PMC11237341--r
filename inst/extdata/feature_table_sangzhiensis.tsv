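name	type	start	end	strand	start_codon	stop_codon	anticodon
tRNA-Phe	tRNA	1	70	H			GAA
12S	rRNA	71	995	H			
tRNA-Val	tRNA	992	1061	H			TAC
16S	rRNA	1065	2658	H			
tRNA-Leu2	tRNA	2657	2731	H			TAA
ND1	PCG	2732	3705	H	ATA	TA(A)	
tRNA-Ile	tRNA	3709	3779	H			GAT
tRNA-Gln	tRNA	3779	3850	L			TTG
tRNA-Met	tRNA	3850	3918	H			CAT
ND2	PCG	3919	4959	H	ATG	TAG	
tRNA-Trp	tRNA	4958	5026	H			TCA
tRNA-Ala	tRNA	5027	5095	L			TGC
tRNA-Asn	tRNA	5096	5168	L			GTT
OL	origin	5171	5198	H			
tRNA-Cys	tRNA	5198	5260	L			GCA
tRNA-Tyr	tRNA	5261	5327	L			GTA
COI	PCG	5329	6885	H	TTG	AGA	
tRNA-Ser2	tRNA	6881	6951	L			TGA
tRNA-Asp	tRNA	6955	7021	H			GTC
COII	PCG	7022	7706	H	ATG	T(AA)	
tRNA-Lys	tRNA	7707	7779	H			TTT
ATP8	PCG	7781	7945	H	ATG	TAA	
ATP6	PCG	7936	8618	H	ATG	TA(A)	
COIII	PCG	8618	9402	H	ATG	TA(A)	
tRNA-Gly	tRNA	9402	9470	H			TCC
ND3	PCG	9471	9815	H	TTG	TAG	
tRNA-Arg	tRNA	9814	9882	H			TCG
ND4L	PCG	9886	10182	H	ATG	TAA	
ND4	PCG	10176	11553	H	ATG	T(AA)	
tRNA-His	tRNA	11560	11628	H			GTG
tRNA-Ser1	tRNA	11635	11696	H			GCT
tRNA-Leu1	tRNA	11697	11769	H			TAG
ND5	PCG	11770	13587	H	ATG	TAA	
ND6	PCG	13595	14104	L	ATG	AGG	
tRNA-Glu	tRNA	14105	14173	L			TTC
Cytb	PCG	14176	15315	H	ATG	TAG	
tRNA-Thr	tRNA	15315	15385	H			TGT
tRNA-Pro	tRNA	15386	15454	L			TGG
D-loop	control	15455	16950	H			
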