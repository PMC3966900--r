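# Published per-mutation detection counts by tissue (number of samples
# showing the mutation) with the pooled count and the number of samples with
# successful output for the assay (total_n / total_tested). Two published
# entries are harmonised to the panel design table: the PTEN frameshift at
# codon 323 is recorded there as T323fs*2 but the design table lists
# N323fs*2; KRAS G13S was reported detected although the design table does
# not carry it (its row is kept here; panel-restricted consumers drop it).
gene	protein_change	nucleotide_change	cervix	endometrium	ovary	vulva	total_n	total_tested
PIK3CA	E545K		33	13	1	1	48	542
PIK3CA	H1047R		2	13	5	0	20	542
PIK3CA	E542K		15	3	1	0	19	542
PIK3CA	R88Q		1	16	1	0	18	542
PIK3CA	M1043I	G>T	0	5	1	0	6	535
PIK3CA	Q546R		0	3	1	0	4	468
PIK3CA	Y1021C		0	4	0	0	4	538
PIK3CA	T1025A		0	4	0	0	4	530
PIK3CA	H1047Y		0	3	0	0	3	541
PIK3CA	E545A		0	2	0	0	2	542
PIK3CA	Q546K		0	2	0	0	2	537
PIK3CA	Q546L		0	1	0	0	1	468
PIK3CA	M1043I	G>A	0	1	0	0	1	535
PIK3CA	M1043V		0	1	0	0	1	490
PIK3CA	H1047L		0	1	0	0	1	542
PTEN	R130G		1	35	1	0	37	542
PTEN	R130fs*4		0	19	2	0	21	545
PTEN	L318fs*2		0	10	0	0	10	542
PTEN	R233*		0	7	0	0	7	543
PTEN	R130*		1	5	0	0	6	542
PTEN	N323fs*2		0	5	0	0	5	542
PTEN	R173C		0	4	0	0	4	540
PTEN	R173H		0	2	1	0	3	539
PTEN	E7*		0	3	0	0	3	545
PTEN	K267fs*31		1	2	0	0	3	542
PTEN	R130L		0	1	0	0	1	544
PTEN	R130P		0	1	0	0	1	544
PTEN	R234W		1	1	0	0	2	495
PTEN	K267fs*9		0	2	0	0	2	536
PTEN	Q214*		1	1	0	0	2	544
PTEN	P248fs*5		0	1	0	0	1	545
PTEN	V290fs*1		0	1	0	0	1	542
KRAS	G12V		2	10	8	0	20	544
KRAS	G12D		4	13	3	0	20	544
KRAS	G13D		0	8	0	0	8	544
KRAS	G12C		1	3	2	0	6	544
KRAS	G12A		0	4	1	0	5	544
KRAS	Q61H	T>G	0	1	1	0	2	542
KRAS	G12S		1	0	0	0	1	544
KRAS	G12R		0	0	1	0	1	544
KRAS	G13S		1	0	0	0	1	465
CTNNB1	S37F		1	10	0	0	11	537
CTNNB1	S45F		1	5	0	0	6	543
CTNNB1	G34R		2	1	0	0	3	537
CTNNB1	T41A		1	3	0	0	4	546
CTNNB1	D32V		0	2	0	0	2	543
CTNNB1	D32Y		0	2	0	0	2	543
CTNNB1	S33F		0	2	0	0	2	542
CTNNB1	D32N		1	1	0	0	2	543
CTNNB1	S37C		0	1	1	0	2	537
CTNNB1	T41I		1	0	0	0	1	542
CTNNB1	S37P		0	1	0	0	1	544
CTNNB1	D32H		0	1	0	0	1	543
CTNNB1	S33A		0	1	0	0	1	544
CTNNB1	S33C		0	1	0	0	1	542
CTNNB1	S33Y		0	1	0	0	1	542
CTNNB1	G34V		0	1	0	0	1	542
CTNNB1	S45P		0	1	0	0	1	542
CTNNB1	G34E		0	0	1	0	1	542
CTNNB1	S37Y		0	0	1	0	1	537
PPP2R1A	R258H		5	3	0	0	8	493
PPP2R1A	R183W		1	6	0	0	7	490
PPP2R1A	P179L		0	5	0	0	5	490
PPP2R1A	P179R		2	1	1	0	4	490
PPP2R1A	R183Q		0	2	0	0	2	463
PPP2R1A	S256F		0	1	1	0	2	463
FBXW7	R465H		2	6	1	0	9	536
FBXW7	R465C		1	3	0	0	4	540
FBXW7	R505C		0	3	0	0	3	542
FGFR2	S252W		0	9	1	0	10	533
FGFR2	K659E		0	2	0	0	2	492
FGFR2	N549K	T>A	1	1	0	0	2	491
FGFR2	N549K	T>G	0	1	0	0	1	541
CDKN2A	R58*		3	0	0	1	4	535
CDKN2A	R80*		0	0	0	2	2	535
CDKN2A	W110*		1	0	1	0	2	541
CDKN2A	P114L		1	0	0	0	1	540
NRAS	G12S		0	2	0	0	2	542
NRAS	Q61L		0	2	0	0	2	541
NRAS	Q61K		0	1	1	0	2	541
NRAS	Q61R		1	0	0	0	1	541
NRAS	G12D		0	1	0	0	1	538
HRAS	G12D		0	0	0	2	2	538
FGFR3	S249C		1	0	0	0	1	523
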