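# Published per-gene detected mutation frequencies: number of mutated samples
# per tissue cohort (cervix N=205, endometrium N=227, ovary N=89, vulva N=25).
# A sample counts once per gene regardless of how many of its mutations hit.
gene	cervix	endometrium	ovary	vulva
PIK3CA	50	67	10	1
PTEN	5	89	3	0
KRAS	9	39	16	0
CTNNB1	7	33	3	0
PPP2R1A	7	18	2	0
FBXW7	3	12	1	0
FGFR2	1	13	1	0
CDKN2A	5	0	1	3
NRAS	1	6	1	0
HRAS	0	0	0	2
FGFR3	1	0	0	0
BRAF	0	0	0	0
FOXL2	0	0	0	0
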