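locus	region	region_class	stem_seq	dg_published	subtype	loop_seq	taxa
1	trnH-psbA_1	IGS	TTTGATTTT	-5.60	A1	TTCCT	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_communis;Lin_erythrocarpa;Lin_glauca;Lin_megaphylla;Lin_nacusua;Lin_praecox;Lin_rubronervia;Sas_tzumu*
1	trnH-psbA_1	IGS	TTTGATTTT	-5.60	A2	TTCAA	Lin_chunii;Lin_floribunda;Lin_metcalfiana;Lin_neesiana*;Lin_reflexa;Lin_sericea*
1	trnH-psbA_1	IGS	TTTGATTTT	-5.60	B	AGGAA	Lin_obtusiloba;Lin_pulcherrima;Lit_japonica
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	A1	AATAGAAC	Lin_chunii;Lin_erythrocarpa;Lin_megaphylla;Lin_metcalfiana;Lin_neesiana;Lin_obtusiloba*;Sas_tzumu*
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	A2	AATAAAAC	Lin_rubronervia
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	A3	ATAGAA	Lin_angustifolia*;Lin_pulcherrima*
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	A4	ATAGAACAGAA	Lin_communis*;Lin_nacusua*
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	B1	GTTCTATT	Act_lancifolia*;Lin_aggregata*;Lin_floribunda;Lin_praecox;Lin_reflexa;Lin_sericea;Lit_japonica
2	trnH-psbA_2	IGS	GGATCAATACCAAACTTCTT	-20.59	B2	TTCTAT	Lin_glauca*
3	rps16-trnQ	IGS	TTAATTCCA	-7.30	A	GCGA	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_glauca;Lin_megaphylla;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lin_reflexa;Lin_rubronervia;Lin_sericea;Lit_japonica;Sas_tzumu
3	rps16-trnQ	IGS	TTAATTCCA	-7.30	B	TCGC	Lin_floribunda
4	rpoB-trnC	IGS	TTTGATCTCC	-7.22	A1	TTATGTCATTAAGGAAACCAAATT	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_floribunda;Lin_glauca;Lin_megaphylla;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lin_reflexa;Lin_rubronervia;Lin_sericea;Lit_japonica;Sas_tzumu
4	rpoB-trnC	IGS	TTTGATCTCC	-7.22	A2	TTATGTCATTAAGGAAACCAAATT	Lin_communis;Lin_nacusua
4	rpoB-trnC	IGS	TTTGATCTCC	-7.22	A3	TTATGTCATTAAGGAAACAAAATT	Lin_erythrocarpa
4	rpoB-trnC	IGS	TTTGATCTCC	-7.22	B	AATTTGGTTTCCTTAATGACATAA	Lin_metcalfiana
5	psbC-trnS	IGS	TGGCTCGGCTA	-12.50	A	GGTGGGA	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_floribunda;Lin_glauca;Lin_megaphylla;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lin_reflexa;Lin_rubronervia;Lin_sericea;Lit_japonica;Sas_tzumu
5	psbC-trnS	IGS	TGGCTCGGCTA	-12.50	B	TCCCACC	Lin_metcalfiana
6	petA-psbJ_1	IGS	TTTCGACACAAGAAAA	-15.98	A	TTCC	Act_lancifolia;Lin_angustifolia*;Lin_communis;Lin_erythrocarpa;Lin_glauca;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_pulcherrima;Lin_sericea;Lit_japonica
6	petA-psbJ_1	IGS	TTTCGACACAAGAAAA	-15.98	B1	GGAA	Lin_aggregata;Lin_chunii;Lin_floribunda;Lin_megaphylla;Lin_praecox;Lin_reflexa;Lin_rubronervia
6	petA-psbJ_1	IGS	TTTCGACACAAGAAAA	-15.98	B2	GCGGAAAATT	Sas_tzumu
7	petA-psbJ_2	IGS	AGTAAGAACTCAATAGGACCTTACCCCT	-30.19	A	CTTTGTCTGATTCG	Lin_chunii;Lin_floribunda;Lin_glauca;Lin_megaphylla;Lin_nacusua;Lin_obtusiloba;Lin_pulcherrima;Lin_reflexa;Lin_sericea;Lit_japonica;Sas_tzumu
7	petA-psbJ_2	IGS	AGTAAGAACTCAATAGGACCTTACCCCT	-30.19	B	CCGAATCAGACAAAGA	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_communis;Lin_erythrocarpa;Lin_metcalfiana;Lin_neesiana;Lin_praecox;Lin_rubronervia
8	rpoA	CDS	ACATCTTC	-6.90	A	TATGC	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_floribunda;Lin_glauca;Lin_megaphylla;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lin_rubronervia;Lin_sericea;Lit_japonica
8	rpoA	CDS	ACATCTTC	-6.90	B	GCATA	Lin_reflexa
9	ycf2	CDS	TTTTTATC	-5.45	A	GAAA	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_floribunda;Lin_megaphylla;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lin_reflexa;Lin_rubronervia;Lin_sericea;Lit_japonica;Sas_tzumu
9	ycf2	CDS	TTTTTATC	-5.45	B	TTTC	Lin_glauca
10	ccsA-ndhD	IGS	AAGTTTTTTCGAACCATTTGAATCA	-27.14	A	CTACT	Act_lancifolia;Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_praecox;Lin_rubronervia;Lin_sericea;Lit_japonica
10	ccsA-ndhD	IGS	AAGTTTTTTCGAACCATTTGAATCA	-27.14	B	AGTAG	Lin_floribunda;Lin_glauca;Lin_megaphylla;Lin_obtusiloba;Lin_pulcherrima;Lin_reflexa;Sas_tzumu
11	ndhA-intron	intron	ACCCCTTTCCT	-9.23	A1	GGAAATAA	Lin_aggregata;Lin_angustifolia;Lin_chunii;Lin_communis;Lin_erythrocarpa;Lin_floribunda;Lin_megaphylla;Lin_metcalfiana;Lin_nacusua;Lin_neesiana;Lin_obtusiloba;Lin_praecox;Lin_pulcherrima;Lit_japonica
11	ndhA-intron	intron	ACCCCTTTCCT	-9.23	A2	GGAAAGAA	Sas_tzumu
11	ndhA-intron	intron	ACCCCTTTCCT	-9.23	B1	TTATTTCC	Act_lancifolia;Lin_glauca;Lin_reflexa;Lin_sericea
11	ndhA-intron	intron	ACCCCTTTCCT	-9.23	B2	TTATTTAC	Lin_rubronervia
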