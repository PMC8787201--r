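gene	block	sequence
ABCC1	18	CUCCCUGCGCCGCCGCCGCCGCCGCCGCAGCGCU
ASH1L	18	CUGCUGCUGCCGCCGCCGCCGCCGCCGCUCCCGC
BTF3L4	18	CUGCUCCCGCCGCCGCCGCCGCCGCCGUCGUCUU
C2CD4C	18	ACUGCGCUGCCGCCGCCGCCGCCGCCCGCAUCGA
CPT1A	18	ACUCCACCGCCGCCGCCGCCGCCGCCGCUGCCGC
EGLN1	18	UCGCCGUCGCCGCCGCCGCCGCCGCCAUGGCCAA
GRIN1	18	UCCGCGGAGCCGCCGCCGCCGCCGCCGGGCCCUU
GTF2E2	18	CCGCCGCUGCCGCCGCCGCCGCCGCCACCGCCAG
MAST1	18	CUCCCCGCGCCGCCGCCGCCGCCGCCUCCGCCGC
MEMO1	18	CCGCUCCUGCCGCCGCCGCCGCCGCCUCCUCAUU
MPRIP	18	AGGCCUGCGCCGCCGCCGCCGCCGCCGUCGCCGC
NOG	18	GCGCGGACGCCGCCGCCGCCGCCGCCGCUGGAGU
RIMS4	18	AGCCGCCCGCCGCCGCCGCCGCCGCCGCGGCCGA
RNF165	18	CGCGCGCAGCCGCCGCCGCCGCCGCCGCGCGAGG
RNF220	18	CUGCCGCUGCCGCCGCCGCCGCCGCCGCUGCCUC
SCAP	18	CCCCCGUCGCCGCCGCCGCCGCCGCCGCAGCUUG
SEPHS1	18	GGGCCCCCGCCGCCGCCGCCGCCGCCGGGCGCGG
SPEN	18	CCGCCGCAGCCGCCGCCGCCGCCGCCCCGGCACC
ABCD3	21	GTAAGGUAGCCGCCGCCGCCGCCGCCGCCGCGUCCCC
ANKH	21	AACCUUCUGCCGCCGCCGCCGCCGCCGCCGUCCCTCC
ANKRD13D	21	GCCCCGCUGCCGCCGCCGCCGCCGCCGCCGCUACTGC
C4orf19	21	GGGACCCCGCCGCCGCCGCCGCCGCCGCCGUCUGGCC
CA10	21	UGGCUGCUGCCGCCGCCGCCGCCGCCGCCGCUGCTAG
DISP2	21	CCGCCACCGCCGCCGCCGCCGCCGCCGCCGCGGCTTC
HS3ST4	21	CGGGGGCUGCCGCCGCCGCCGCCGCCGCCGCGAGCCG
JARID2	21	GUGGUGCUGCCGCCGCCGCCGCCGCCGCCGCUGGAGT
RGP1	21	CAGCGGACGCCGCCGCCGCCGCCGCCGCCGCGUACCT
UBE2R2	21	GGCCCGGCGCCGCCGCCGCCGCCGCCGCCGCGAUGGC
USP25	21	GCGCCACCGCCGCCGCCGCCGCCGCCGCCGCGGGGGC
AFF2	24	CAGCCGCUGCCGCCGCCGCCGCCGCCGCCGCCGCGCCGCC
CUL3	24	GAGUCCGAGCCGCCGCCGCCGCCGCCGCCGCCCCCGCCGC
FAM50A	24	CGCCGCCCGCCGCCGCCGCCGCCGCCGCCGCCGCUGCCAU
GSK3B	24	GGGCUUGUGCCGCCGCCGCCGCCGCCGCCGCCCGGGCCAA
MAP2K3	24	CCGCAGUCGCCGCCGCCGCCGCCGCCGCCGCCGCUGCUCC
MSI1	24	CGCCGAGCGCCGCCGCCGCCGCCGCCGCCGCCGCUCCGCU
MTHFD1L	24	UCCUUCCCGCCGCCGCCGCCGCCGCCGCCGCCUGCUCCCC
NCKAP1	24	CCGGAGACGCCGCCGCCGCCGCCGCCGCCGCCACACCUAG
RPRD2	24	CCGCUCCCGCCGCCGCCGCCGCCGCCGCCGCCAGAGGAGC
UBTF	24	CAGCCACAGCCGCCGCCGCCGCCGCCGCCGCCACAGCAGC
TCEA1	24	GAGCCGGAGCCGCCGCCGCCGCCGCCGCCGCCGCGGGCUU
THOC7	24	CAGCUUGCGCCGCCGCCGCCGCCGCCGCCGCCGCGCACGC
USP7	24	GGCCGCCCGCCGCCGCCGCCGCCGCCGCCGCCCCGGCUCG
ZNF219	24	CGCCGCCCGCCGCCGCCGCCGCCGCCGCCGCCCGCUCCGC
SBF1	27-48	ACCUGGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCGGAGCGAACCAGGGGUGUCCGGGGT
SMAD9	27-48	GCUGGGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCUGCUGCAGCCGCUGUCUCGGUCCCC
BCL11A	27-48	CCGCCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCCGCCCCGCAGCCCACCAUGUCTCG
WBP4	27-48	GCUGCUGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCUGCUGCUGCCCACACGCUCCCG
GNB2	27-48	AUCCGCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCUCCGCCGCGGAGGAAGAC
KIF3B	27-48	GCCCCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCCGCUUUCGGCUCGGGCCT
NDRG3	27-48	CCUCUCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCUGCUGCUGCACTG
BCL2L11	27-48	GCCGCUGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCACUACCACCACT
RHOT1	27-48	GACUCGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCACAGCC
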