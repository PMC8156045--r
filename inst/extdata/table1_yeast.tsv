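domain_id	ligands	mai	organism	lsi_printed	pss_printed	pdb
Bem1	4	nd	yeast	10	0	2v6v,2czo
Bem3	3	nd	yeast	10	2	6fsf
Grd19	3	nd	yeast	10	3	1ocs,1ocu
Mdm1	3	nd	yeast	10	0	
Mvp1	3	nd	yeast	10	0	6p0x
Spo14	3	nd	yeast	10	0	
Vam7	3	nd	yeast	10	1	1kmd
Ykr078w	3	nd	yeast	10	0	
Ypt35	3	nd	yeast	10	0	
Vps5	3,5	nd	yeast	9	0	
Atg20	3,4,5	nd	yeast	8	1	
Snx4	3,45	nd	yeast	8	0	
Snx41	3,4,5	nd	yeast	8	7	
Vps17	3,4,5,34,35,45	nd	yeast	2	1	
Ypr097w	3,4,5,34,35,45,345	nd	yeast	1	2	
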