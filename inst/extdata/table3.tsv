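gene	block	sequence	peptide
ATOH8	18	CUCCCCACGCCGCCGCCGCCGCCGCCUCCUGCGC	PPPPPP
GABBR2	18	CAGCCCGGGCCGCCGCCGCCGCCGCCACCGCCGC	PPPPPP
FAM117B	18	CCCCCACGGCCGCCGCCGCCGCCGCCGCUGCUGG	PPPPPP
FOXG1	18	CAGCAGCAGCCGCCGCCGCCGCCGCCCCCGGCAC	PPPPPP
FOXK1	18	CCGCCCGGGCCGCCGCCGCCGCCGCCACCGCCGC	PPPPPP
GPR150	18	UCGCCGCUGCCGCCGCCGCCGCCGCCAACGUCCC	PPPPPP
IRX5	18	ACCCCGCGGCCGCCGCCGCCGCCGCCUUCUCCUC	PPPPPP
LOXL1	18	CCCUACGUGCCGCCGCCGCCGCCGCCCCCCGACG	PPPPPP
LTBP1	18	CUCAGACCGCCGCCGCCGCCGCCGCCGGAGCCUG	RPPPPP
MECP2	18	GGAAAATGGCCGCCGCCGCCGCCGCCGCGCCGAG	PPPPPP
TMEM121	18	AACUCGGUGCCGCCGCCGCCGCCGCCGCUGCACG	PPPPPP
TSPYL2	18	CCGCCCCCGCCGCCGCCGCCGCCGCCGCUCCUCC	PPPPPP
TPRN	18	CGCCCCCCGCCGCCGCCGCCGCCGCCCGCGCCGC	PPPPPP
ZCCHC2	18	CGCCCCCCGCCGCCGCCGCCGCCGCCCGCGGGCC	PPPPPP
ZNF367	18	GAGAACCCGCCGCCGCCGCCGCCGCCCGUCAUCU	PPPPPP
ZNF839	18	AAGGCGCAGCCGCCGCCGCCGCCGCCCCCCUUCG	PPPPPP
FOXD1	18	CGCAGCGCGCCGCCGCCGCCGCCGCCUUCCACCC	AAAAAA
CASZ1	18	GCGAGGGCGCCGCCGCCGCCGCCGCCGCAGCUGG	AAAAAA
GPR88	18	CCGGCUGCGCCGCCGCCGCCGCCGCCUUCCCGGG	AAAAAA
FBXL17	18	UAUCCUCGGCCGCCGCCGCCGCCGCCGCUGCCGC	AAAAAA
HOXA2	18	UUCUGCCGGCCGCCGCCGCCGCCGCCACCGCCGC	AAAAAA
HOXA13	18	CCGCUGCAGCCGCCGCCGCCGCCGCCGCGUCGUC	AAAAAA
IRX2	18	CGGCCGACGCCGCCGCCGCCGCCGCCGGCUUCCC	AAAAAA
IRX3	18	UCUCUCCGGCCGCCGCCGCCGCCGCCGCUCACAG	AAAAAA
IRX4	18	CAGCCACCGCCGCCGCCGCCGCCGCCACCUCCCU	AAAAAA
LCORL	18	CCGCUGCUGCCGCCGCCGCCGCCGCCGCUCAGUG	AAAAAA
LHFPL3	18	CCGCCGCUGCCGCCGCCGCCGCCGCCGCGAUGCU	AAAAAA
NANOS1	18	GCGCGCCCGCCGCCGCCGCCGCCGCCACCACCAC	AAAAAA
POU3F3	18	UGCCCCACGCCGCCGCCGCCGCCGCCGCUGCCGC	AAAAAA
SOX12	18	AGGGGGCGGCCGCCGCCGCCGCCGCCUCCCCGAC	AAAAAA
SOX21	18	CCGCCGCUGCCGCCGCCGCCGCCGCCGCGGGCAG	AAAAAA
SP8	18	GCGCCGCAGCCGCCGCCGCCGCCGCCGCAGCCGC	AAAAAA
UNCX	18	CUUCCAACGCCGCCGCCGCCGCCGCCGCGGGGCU	AAAAAA
ARX	21	CGGCCGCUGCCGCCGCCGCCGCCGCCGCCUUCCCGAG	AAAAAAA
DGKI	21	CUCCUGCAGCCGCCGCCGCCGCCGCCGCCAGCCCGCC	AAAAAAA
GSG1L	21	CCGCCCCCGCCGCCGCCGCCGCCGCCGCCACCGCCUC	AAAAAAA
JUND	21	CGGCCGCUGCCGCCGCCGCCGCCGCCGCCGGGGGGCC	AAAAAAA
SKOR2	21	CCGGCCCCGCCGCCGCCGCCGCCGCCGCCCCCGCCGC	PPPPPPP
CEBPA	21	CCUUACCAGCCGCCGCCGCCGCCGCCGCCCUCGCACC	PPPPPPP
CHD3	21	CUCUUCCCGCCGCCGCCGCCGCCGCCGCCACCGCUGC	PPPPPPP
CTNND2	21	GAGCCCGCGCCGCCGCCGCCGCCGCCGCCGCGGGAGC	PPPPPPP
HCN2	21	GCGCCGGGGCCGCCGCCGCCGCCGCCGCCCGCGCCCC	PPPPPPP
HTT	21	CCGCCACCGCCGCCGCCGCCGCCGCCGCCUCCUCAGC	PPPPPPP
SOBP	21	CCCGAGCAGCCGCCGCCGCCGCCGCCGCCCGCGCCCC	PPPPPPP
TGFBR3L	21	CCUCUGACGCCGCCGCCGCCGCCGCCGCCAUCGCGGU	PPPPPPP
SLC24A3	21	CGCGCGUCGCCGCCGCCGCCGCCGCCGCCGGAGGGAC	RRRRRRR
CCDC177	24	GCCCCGCGGCCGCCGCCGCCGCCGCCGCCGCCGCGGCCUC	AAAAAAAA
IRS2	24	AGCCCAGGGCCGCCGCCGCCGCCGCCGCCGCCGUGCCUUC	AAAAAAAA
MEGF9	24	UGUGCUGCGCCGCCGCCGCCGCCGCCGCCGCCGUCGCCUC	AAAAAAAA
SKIDA1	24	ACCCGGCAGCCGCCGCCGCCGCCGCCGCCGCCGCUGCUGC	AAAAAAAA
ZIC3	24	CAACCCACGCCGCCGCCGCCGCCGCCGCCGCCGCUGCCUU	AAAAAAAA
FMNL1	24	GUGCCUCCGCCGCCGCCGCCGCCGCCGCCGCCUCCCGGAG	PPPPPPPP
GBX2	24	GUAGUGCUGCCGCCGCCGCCGCCGCCGCCGCCCGCGCUGC	PPPPPPPP
MMP24	24	GCGCCGGGGCCGCCGCCGCCGCCGCCGCCGCCGGGCCAGG	PPPPPPPP
TRIM67	24	CUGGUGCAGCCGCCGCCGCCGCCGCCGCCGCCCGCCGAGG	PPPPPPPP
DLX6	27-36	CCTGCCCGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCAGCCGCCTCGCAGCA	PPPPPPPPP
DMRTA2	27-36	GCGTCGACGCCGCCGCCGCCGCCGCCGCCGCCGCCGGGGGGCCTGGGCTGCC	AAAAAAAAA
FOXF2	27-36	CGCCGCCCGCCGCCGCCGCCGCCGCCGCCGCCGCCCCGGAGACCACCTCCTC	AAAAAAAAA
IRF2BPL	27-36	TAAGCGCTGCCGCCGCCGCCGCCGCCGCCGCCGCCGCTGCGGTGGAACAGCG	AAAAAAAAA
MNX1	27-36	CGGCCGCTGCCGCCGCCGCCGCCGCCGCCGCCGCCGCTGGGGGCCTGGCGCT	AAAAAAAAA
NKX2-3	27-36	CGGCCGCGGCCGCCGCCGCCGCCGCCGCCGCCGCCGCAGCAGCGGCGGCCTA	AAAAAAAAA
ZNF703	27-36	TGGGCAGCGCCGCCGCCGCCGCCGCCGCCGCCGCCTCCTGCCATCTGCACCT	AAAAAAAAA
ZSWIM6	27-36	CCGCCGCTGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCGGGGGCCGGGGC	AAAAAAAAAA
CASKIN1	27-36	CCCCGCGAGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCGCCCCCCGCCCC	AAAAAAAAAA
FOXE1	27-36	GCTGCCCAGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCATCTTCCCAGG	AAAAAAAAAAA
ZIC5	27-36	GCCGGGCTGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCGCCACCGCCCC	PPPPPPPPPPP
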