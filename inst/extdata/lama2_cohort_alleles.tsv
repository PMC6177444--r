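subject	family	phenotype_group	allele1	allele1_derivation	allele2	allele2_derivation	curator_note
P1	F01	MDC1A	DEL:129187644-129212825	maternal	SNV	paternal	
P2	F02	MDC1A	DEL:129185304-129210133	maternal	SNV	paternal	
P3	F03	MDC1A	DEL:129355433-129402434	paternal	SNV	maternal	
P4	F04	MDC1A	DEL:129221788-129488858	paternal	SNV	maternal	
P5	F05	MDC1A	DEL:129354701-129548523	maternal	SNV	paternal	
P6	F06	MDC1A	DEL:129379289-129454975	maternal	DEL:129379289-129454975	paternal	
P7	F07	MDC1A	DEL:129414981-129420437	paternal	SNV	maternal	
P8	F08	MDC1A	DEL:129414981-129420437	maternal	DEL:129414981-129420437	paternal	
P9	F09	MDC1A	DEL:129414981-129420437	maternal	DEL:129414981-129420437	paternal	
P10	F10	MDC1A	DEL:129414981-129420437	paternal	SNV	maternal	
P11	F11	MDC1A	DEL:129414981-129420437	paternal	SNV	maternal	
P12	F12	MDC1A	DEL:129414981-129420437	paternal	SNV	maternal	
P13	F13	MDC1A	DEL:129414981-129420437	maternal	SNV	paternal	
P14	F14	MDC1A	DEL:129414981-129420437	paternal	SNV	maternal	
P15	F15	MDC1A	DEL:129423549-129465235	maternal	SNV	paternal	
P16	F16	MDC1A	DUP:129440069-129478884	maternal	SNV	paternal	
P17	F17	MDC1A	DEL:129488856-129544038	paternal	SNV	maternal	
P18	F18	MDC1A	DEL:129566786-129578227	maternal	SNV	paternal	
P19	F19	MDC1A	DEL:129612189-129613535	paternal	SNV	maternal	
P20	F20	MDC1A	DEL:129658427-129664812	maternal	SNV	paternal	
P21	F21	LGMD	DEL:129710417-open	paternal	SNV	maternal	
P22	F22	MDC1A	DEL:129746506-129775772+129776069-129779042	maternal	SNV	paternal	
P23	F23	MDC1A	DEL:129778345-129782637	maternal	SNV	paternal	
P24	F24	MDC1A	DEL:129778345-129782637	paternal	SNV	maternal	
P25	F25	MDC1A	DEL:129778271-129813338	paternal	SNV	maternal	
P26	F26	MDC1A	DEL:129816374-129833601	paternal	SNV	maternal	
P27	F27	MDC1A	DEL:129816374-129833601	paternal	SNV	maternal	
P28	F28	LGMD	DEL:129816374-129833601	maternal	SNV	paternal	
P29	F29	MDC1A	DEL:129833559-129833615	maternal	SNV	paternal	
P3r	F03	MDC1A	DEL:129355433-129402434	maternal	SNV	paternal	affected relative of the family proband; family placement synthetic
P5r	F05	MDC1A	DEL:129354701-129548523	maternal	SNV	paternal	affected relative of the family proband; family placement synthetic
P6r	F06	MDC1A	DEL:129379289-129454975	maternal	SNV	paternal	affected relative of the family proband; family placement synthetic
P17r	F17	MDC1A	DEL:129488856-129544038	maternal	SNV	paternal	affected relative of the family proband; family placement synthetic
P22r	F22	MDC1A	DEL:129746506-129775772+129776069-129779042	maternal	SNV	paternal	affected relative of the family proband; family placement synthetic
S01	F30	MDC1A	SNV	maternal	SNV	paternal	
S02	F31	MDC1A	SNV	maternal	SNV	paternal	
S03	F32	MDC1A	SNV	maternal	SNV	paternal	
S04	F33	MDC1A	SNV	maternal	SNV	paternal	
S05	F34	MDC1A	SNV	maternal	SNV	paternal	
S06	F35	MDC1A	SNV	maternal	SNV	paternal	
S07	F36	MDC1A	SNV	maternal	SNV	paternal	
S08	F37	MDC1A	SNV	maternal	SNV	paternal	
S09	F38	MDC1A	SNV	maternal	SNV	paternal	
S10	F39	MDC1A	SNV	maternal	SNV	paternal	
S11	F40	MDC1A	SNV	maternal	SNV	paternal	
S12	F41	MDC1A	SNV	maternal	SNV	paternal	
S13	F42	MDC1A	SNV	maternal	SNV	paternal	
S14	F43	MDC1A	SNV	maternal	SNV	paternal	
S15	F44	MDC1A	SNV	maternal	SNV	paternal	
S16	F45	MDC1A	SNV	maternal	SNV	paternal	
S17	F46	MDC1A	SNV	maternal	SNV	paternal	
S18	F47	MDC1A	SNV	maternal	SNV	paternal	
S19	F48	MDC1A	SNV	maternal	SNV	paternal	
S20	F49	MDC1A	SNV	maternal	SNV	paternal	
S21	F50	MDC1A	SNV	maternal	SNV	paternal	
S22	F51	MDC1A	SNV	maternal	SNV	paternal	
S23	F52	MDC1A	SNV	maternal	SNV	paternal	
S24	F53	MDC1A	SNV	maternal	SNV	paternal	
S25	F54	MDC1A	SNV	maternal	SNV	paternal	
S26	F55	MDC1A	SNV	maternal	SNV	paternal	
S27	F56	MDC1A	SNV	maternal	SNV	paternal	
S28	F57	MDC1A	SNV	maternal	SNV	paternal	
S29	F58	MDC1A	SNV	maternal	SNV	paternal	
S30	F59	MDC1A	SNV	maternal	SNV	paternal	
S31	F60	MDC1A	SNV	maternal	SNV	paternal	
S32	F61	MDC1A	SNV	maternal	SNV	paternal	
S33	F62	MDC1A	SNV	maternal	SNV	paternal	
S34	F63	MDC1A	SNV	maternal	SNV	paternal	
S35	F64	MDC1A	SNV	maternal	SNV	paternal	
S36	F65	MDC1A	SNV	maternal	SNV	paternal	
S37	F66	MDC1A	SNV	maternal	SNV	paternal	
S38	F67	MDC1A	SNV	maternal	SNV	paternal	
S39	F68	MDC1A	SNV	maternal	SNV	paternal	
S40	F69	MDC1A	SNV	maternal	SNV	paternal	
S41	F70	MDC1A	SNV	maternal	SNV	paternal	
S42	F71	MDC1A	SNV	maternal	SNV	paternal	
S43	F72	MDC1A	SNV	maternal	SNV	paternal	
S44	F73	MDC1A	SNV	maternal	SNV	paternal	
S45	F74	MDC1A	SNV	maternal	SNV	paternal	
S46	F75	MDC1A	SNV	maternal	SNV	paternal	
S47	F76	MDC1A	SNV	maternal	SNV	paternal	
S48	F77	MDC1A	SNV	maternal	SNV	paternal	
S49	F78	MDC1A	SNV	maternal	SNV	paternal	
S50	F79	MDC1A	SNV	maternal	SNV	paternal	
S51	F80	MDC1A	SNV	maternal	SNV	paternal	
S52	F81	MDC1A	SNV	maternal	SNV	paternal	
S53	F82	MDC1A	SNV	maternal	SNV	paternal	
S54	F83	MDC1A	SNV	maternal	SNV	paternal	
S55	F84	MDC1A	SNV	maternal	SNV	paternal	
S56	F85	MDC1A	SNV	maternal	SNV	paternal	
S57	F86	MDC1A	SNV	maternal	SNV	paternal	
S58	F87	MDC1A	SNV	maternal	SNV	paternal	
S59	F88	MDC1A	SNV	maternal	SNV	paternal	
S60	F89	MDC1A	SNV	maternal	SNV	paternal	
S61	F90	MDC1A	SNV	maternal	SNV	paternal	
S62	F91	MDC1A	SNV	maternal	SNV	paternal	
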