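domain_id	ligands	mai	organism	lsi_printed	pss_printed	pdb
PLD1	345	S	human	10	1	IT
PLD2	45	W	human	10	16	IT
PXK	3	W	human	10	4	IT
p40phox	3	S	human	10	1	1h6h
SH3PXD2A	3	S	human	10	1	IT
SNX1	34	S	human	10	15	2i4k
SNX2	34	S	human	10	17	IT
SNX3	3	S	human	10	13	5f0j
SNX4	3	W	human	10	3	IT
SNX6	4	W	human	10	2	IT
SNX7	3	W	human	10	3	IT
SNX8	3	S	human	10	0	IT
SNX10	3	W	human	10	0	4on3
SNX12	3	S	human	10	8	2csk
SNX16	3	S	human	10	2	5gw0
SNX17	3	S	human	10	9	IT
SNX19	3	S	human	10	2	IT
SNX27	3	S	human	10	6	4has
SNX30	3	W	human	10	1	IT
SNX31	3	S	human	10	1	IT
NOXO1B	45,345	W	human	9	0	2l73
SNX18	34,45	S	human	9	0	IT
SNX33	34,45	S	human	9	9	IT
ARHGAP32	3,4,5	W	human	8	5	IT
NISCH	3,34	W	human	8	6	3p0c
PIK3C2A	34,35,45	S	human	8	1	2ar5
PIK3C2B	34,45,345	S	human	8	2	IT
SGK3	3,34	S	human	8	2	1xte
SH3PXD2B	3,34	S	human	8	6	IT
SNX13	3,34	W	human	8	3	IT
SNX21	3,45	S	human	8	6	IT
NOXO1G	4,5,35	W	human	7	2	IT
PIK3C2G	34,35,45,345	W	human	7	0	2wwe
SNX25	34,35,45,345	S	human	7	2	5woe
SNX29	3,34,45	S	human	7	0	IT
KIF16B	3,34,45,345	S	human	6	1	2v14
p47phox	3,34,45,345	S	human	6	6	1kq6
RPS6KC1	3,34,45,345	S	human	6	6	IT
SNX5	3,34,35,45	W	human	6	1	3hpc
SNX9	3,34,45,345	W	human	6	4	2raj
SNX22	3,34,45,345	S	human	6	2	2ett
SNX24	3,34,35,45	S	human	6	7	4az9
HS1BP3	3,34,35,45,345	S	human	5	0	IT
SNX20	3,5,35,45	S	human	5	2	IT
SNX15	3,4,34,35,45,345	S	human	3	0	IT
SNX11	3,4,5,34,35,45,345	S	human	1	0	4ikb
ARHGAP33		N	human	0	0	IT
SNX14		N	human	0	1	IT
SNX32		N	human	0	3	6e8r
PXDC1	nd	nd	human	nd	0	IT
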