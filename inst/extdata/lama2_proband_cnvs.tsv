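subject	family	phenotype_group	cnv_name	type	exon_start	exon_end	frame_label	zygosity	cnv_derivation
P1	F01	MDC1A	Exon1del	DEL	1	1	out_of_frame	het	maternal
P2	F02	MDC1A	Exon1del	DEL	1	1	out_of_frame	het	maternal
P3	F03	MDC1A	Exon2-3del	DEL	2	3	out_of_frame	het	paternal
P4	F04	MDC1A	Exon2-9del	DEL	2	9	in_frame	het	paternal
P5	F05	MDC1A	Exon2-12del	DEL	2	12	out_of_frame	het	maternal
P6	F06	MDC1A	Exon3-4del	DEL	3	4	out_of_frame	hom	both
P7	F07	MDC1A	Exon4del	DEL	4	4	in_frame	het	paternal
P8	F08	MDC1A	Exon4del	DEL	4	4	in_frame	hom	both
P9	F09	MDC1A	Exon4del	DEL	4	4	in_frame	hom	both
P10	F10	MDC1A	Exon4del	DEL	4	4	in_frame	het	paternal
P11	F11	MDC1A	Exon4del	DEL	4	4	in_frame	het	paternal
P12	F12	MDC1A	Exon4del	DEL	4	4	in_frame	het	paternal
P13	F13	MDC1A	Exon4del	DEL	4	4	in_frame	het	maternal
P14	F14	MDC1A	Exon4del	DEL	4	4	in_frame	het	paternal
P15	F15	MDC1A	Exon5del	DEL	5	5	in_frame	het	maternal
P16	F16	MDC1A	Exon5-8dup	DUP	5	8	in_frame	het	maternal
P17	F17	MDC1A	Exon10-12del	DEL	10	12	out_of_frame	het	paternal
P18	F18	MDC1A	Exon13-14del	DEL	13	14	out_of_frame	het	maternal
P19	F19	MDC1A	Exon20del	DEL	20	20	out_of_frame	het	paternal
P20	F20	MDC1A	Exon30del	DEL	30	30	out_of_frame	het	maternal
P21	F21	LGMD	Exon36-65del	DEL	36	65	out_of_frame	het	paternal
P22	F22	MDC1A	Exon41-47del	DEL_NML_DEL	41	47	out_of_frame	het	maternal
P23	F23	MDC1A	Exon49del	DEL	49	49	out_of_frame	het	maternal
P24	F24	MDC1A	Exon49del	DEL	49	49	out_of_frame	het	paternal
P25	F25	MDC1A	Exon49-57del	DEL	49	57	out_of_frame	het	paternal
P26	F26	MDC1A	Exon59-63del	DEL	59	63	in_frame	het	paternal
P27	F27	MDC1A	Exon59-63del	DEL	59	63	in_frame	het	paternal
P28	F28	LGMD	Exon59-63del	DEL	59	63	in_frame	het	maternal
P29	F29	MDC1A	Exon63del-56bp	DEL	63	63	out_of_frame	het	maternal
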