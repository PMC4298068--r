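gene_id	transcript_id	exon_id	chrom	start	end	strand	biotype
RGN	RGN-001	E01	chrX	1	100	-	protein_coding
RGN	RGN-001	E02	chrX	701	800	-	protein_coding
RGN	RGN-001	E04	chrX	2101	2200	-	protein_coding
RGN	RGN-001	E05	chrX	2801	2900	-	protein_coding
RGN	RGN-001	E06	chrX	3501	3600	-	protein_coding
RGN	RGN-001	E08	chrX	4901	5000	-	protein_coding
RGN	RGN-001	E10	chrX	6301	6400	-	protein_coding
RGN	RGN-001	E11	chrX	7001	7100	-	protein_coding
RGN	RGN-001	E12	chrX	7701	7800	-	protein_coding
RGN	RGN-001	E13	chrX	8401	8500	-	protein_coding
RGN	RGN-001	E15	chrX	9801	9900	-	protein_coding
RGN	RGN-002	E02	chrX	701	800	-	protein_coding
RGN	RGN-002	E04	chrX	2101	2200	-	protein_coding
RGN	RGN-002	E06	chrX	3501	3600	-	protein_coding
RGN	RGN-002	E07	chrX	4201	4300	-	protein_coding
RGN	RGN-002	E08	chrX	4901	5000	-	protein_coding
RGN	RGN-002	E10	chrX	6301	6400	-	protein_coding
RGN	RGN-002	E12	chrX	7701	7800	-	protein_coding
RGN	RGN-002	E14	chrX	9101	9200	-	protein_coding
RGN	RGN-201	E03	chrX	1401	1500	-	protein_coding
RGN	RGN-201	E04	chrX	2101	2200	-	protein_coding
RGN	RGN-201	E05	chrX	2801	2900	-	protein_coding
RGN	RGN-201	E06	chrX	3501	3600	-	protein_coding
RGN	RGN-201	E08	chrX	4901	5000	-	protein_coding
RGN	RGN-201	E09	chrX	5601	5700	-	protein_coding
RGN	RGN-201	E10	chrX	6301	6400	-	protein_coding
RGN	RGN-201	E12	chrX	7701	7800	-	protein_coding
RGN	RGN-201	E13	chrX	8401	8500	-	protein_coding
RGN	RGN-202	E01	chrX	1	100	-	protein_coding
RGN	RGN-202	E04	chrX	2101	2200	-	protein_coding
RGN	RGN-202	E06	chrX	3501	3600	-	protein_coding
RGN	RGN-202	E08	chrX	4901	5000	-	protein_coding
RGN	RGN-202	E10	chrX	6301	6400	-	protein_coding
RGN	RGN-202	E12	chrX	7701	7800	-	protein_coding
RGN	RGN-202	E15	chrX	9801	9900	-	protein_coding
RGN	RGN-003	E01	chrX	1	100	-	processed_transcript
RGN	RGN-003	E02	chrX	701	800	-	processed_transcript
RGN	RGN-003	E03	chrX	1401	1500	-	processed_transcript
RGN	RGN-004	E13	chrX	8401	8500	-	processed_transcript
RGN	RGN-004	E14	chrX	9101	9200	-	processed_transcript
RGN	RGN-004	E15	chrX	9801	9900	-	processed_transcript
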