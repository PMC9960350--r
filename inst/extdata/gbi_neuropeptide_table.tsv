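name	ids	source_ids	locus	methods
Adipokinetic hormone (AKH)	GBI_30800-RA	TRINITY_DN4202_c0_g1_i2	Scaffold206:697999..707834(+)	T
AKH/Corazonin-related peptide (ACP)	GBI_32000-RA	TRINITY_DN11870_c1_g1_i1.p3		T
Allatostatin A (Ast A)	GBI_32100-RA;GBI_32200-RA;GBI_04463-RA	TRINITY_DN797_c0_g1_i3.p1;TRINITY_DN797_c0_g1_i5.p1	Scaffold20:11377336..11377923(-)	D,T
Allatostatin B (Ast B)	GBI_04462-RB	STRG.5257.1.p1	Scaffold20:10912781..10975738(-)	S
Allatostatin C (Ast C)	GBI_31000-RA;GBI_31000-RB;GBI_31000-RC	STRG.23460.1.p1;STRG.23460.2.p1;STRG.23460.4.p1	Scaffold437:197807..241684(-)	S
Allatostatin CC (Ast CC)	GBI_32300-RA;GBI_32400-RA	TRINITY_DN78939_c0_g1_i1.p3;TRINITY_DN82217_c0_g1_i1.p3		T
Allatostatin CCC (Ast CCC)	GBI_09174-RA;GBI_09174-RB		Scaffold60:395418..593331(+)	D
Allatotropin	GBI_32500-RA;GBI_32600-RA	TRINITY_DN12736_c4_g1_i1.p1;TRINITY_DN12736_c2_g1_i1.p3		T
Bursicon-alpha	GBI_18108-RA		Scaffold254:577937..579923(-)	D
Bursicon-beta	GBI_18109-RA		Scaffold254:587165..588284(+)	D
CAPA	GBI_04457-RB		Scaffold20:9936553..9977407(+)	D
Corazonin	GBI_30500-RA	STRG.10676.1.p1	Scaffold62:3436728..3448223(-)	S
Crustacean cardioactive peptide (CCAP)	GBI_09648-RA		Scaffold65:3361094..3402145(+)	D
CCHamide-1	GBI_32700-RA	TRINITY_DN15771_c0_g2_i1.p1		T
CCHamide-2	GBI_32800-RA	TRINITY_DN5060_c0_g3_i2.p4		T
Diapause hormone (DH/PBAN-like peptide)	GBI_30900-RA	STRG.20898.1.p1	Scaffold262:1299901..1301218(+)	S
Diuretic hormone 31 (CT/DH)	GBI_08745-RB;GBI_08745-RC	STRG.10008.1.p1;STRG.10008.2.p1	Scaffold56:1634530..1842684(+)	S
Corticotropin releasing factor-like diuretic hormone (CRF/DH)	GBI_32900-RA	TRINITY_DN2611_c0_g1_i1.p2		T
Ecdysis triggering hormone (ETH)	GBI_07130-RA		Scaffold39:4483375..4511070(+)	D
Eclosion hormone	GBI_03726-RA		Scaffold15:14005275..14019193(+)	D
Elevenin	GBI_30700-RA;GBI_30700-RB;GBI_30700-RC	STRG.16982.1.p1;STRG.16982.2.p3;STRG.16982.3.p3	Scaffold153:2142142..2267228(+)	S
EFLamide				
FMRFamide	GBI_14002-RA		Scaffold134:2784690..2789881(-)	D
Glycoprotein hormone A2 (GPA2)	GBI_30100-RA;GBI_30100-RB;GBI_30100-RC	STRG.7443.1.p1;STRG.7443.2.p1;STRG.7443.4.p1	Scaffold34:5739999..5757709(-)	S
Glycoprotein hormone B5 (GPB5)	GBI_30400-RA	STRG.8674.2.p1	Scaffold43:6774211..6779917(-)	S
Insulin-like peptide	GBI_11105-RA		Scaffold84:3089694..3140894(-)	D
Ion transport peptide and ion transport peptide-like (ITP and ITPL)	GBI_18262-RG;GBI_18262-RH		Scaffold259:893509..930810(-)	D
Kinin (Leucokinin)	GBI_30200-RA;GBI_33200-RA	STRG.7466.1.p1;TRINITY_DN110628_c0_g1_i1.p2	Scaffold34:8543640..8544062(-)	S,T
Myosuppressin	GBI_33000-RA	TRINITY_DN4455_c0_g1_i4.p2		T
Natalisin	GBI_30300-RA	STRG.7468.1.p4	Scaffold34:8647546..8652008(-)	T
Neuropeptide F1a (NPF1a)	GBI_33300-RA	TRINITY_DN14629_c0_g1_i2.p2		
Neuropeptide F1b (NPF1b)	GBI_33100-RA	TRINITY_DN14629_c0_g1_i6.p2		T
Neuroparsin precursor (NPP) isoform 1	GBI_01783-RB	STRG.2256.1.p1	Scaffold7:15634784..15638238(+)	S
Neuroparsin precursor (NPP) isoform 2	GBI_06742-RA;GBI_06742-RB		Scaffold35:7759086..7774792(+)	D
Orcokinin	GBI_02308-RA;GBI_02308-RB	STRG.2901.1.p1	Scaffold9:16015120..16184531(-)	D,S
Pigment dispersing factor (PDF)	GBI_30600-RA	TRINITY_DN4557_c4_g1_i1	Scaffold130:1613008..1616041(-)	T
Proctolin	GBI_30000-RA	TRINITY_DN7875_c1_g1_i1	Scaffold4:15016980..15064115(-)	T
RYamide	GBI_11027-RA		Scaffold83:5210571..5235250(-)	D
Short neuropeptide F (sNPF)	GBI_09088-RA;GBI_09088-RB;GBI_09088-RC;GBI_09088-RD		Scaffold59:3780407..4100907(+)	D
SIFamide	GBI_07129-RA		Scaffold39:4382305..4384876(+)	D
Sulfakinin	GBI_05512-RA		Scaffold28:3070275..3081238(-)	D
Tachykinin				
Trissin	GBI_01877-RA;GBI_01877-RB		Scaffold8:2096488..2133885(-)	D
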