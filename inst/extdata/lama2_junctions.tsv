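subject	structure	junction_index	left_pos	right_pos	printed_length_bp	repeats	microhomology	insertion	blunt	insertion_origin	printed_mechanism	errors_near_breakpoint	resolved	curator_note
P1	DEL	1	129187644	129212825	25181		CA		no		NHEJ or MMBIR		yes	
P2	DEL	1	129185304	129210133	24829		TCTT		no		NHEJ or MMBIR		yes	
P3	DEL	1	129355433	129402434	47001		TAA		no		NHEJ or MMBIR	G>T@129355411;C>T@129402537	yes	
P4	DEL	1	129221788	129488858	267070			A	no	random	NHEJ	C>G@129488876;T>A@129488886	yes	
P5	DEL	1	129354701	129548523	193822				yes		NHEJ		yes	
P6	DEL	1	129379289	129454975	75686			TCGTAAAATACACACACACACACACTCC	no	templated	NHEJ	A>C@129378992	yes	28-bp insertion maps to reference near breakpoint (templated); narrative attributes serial replication stalling
P7	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P8	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P9	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P10	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P11	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P12	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P13	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P14	DEL	1	129414981	129420437	5465		AACAA		no		NHEJ or MMBIR		yes	printed length 5465 != coordinate difference 5456; founder exon-4 allele
P15	DEL	1	129423549	129465235	41686		GAT		no		NHEJ or MMBIR	insA@129423453-129423454	yes	
P16	DUP	1	129440069	129478884	38815		A		no		NHEJ or MMBIR		yes	tandem duplication, head-to-tail junction
P17	DEL	1	129488856	129544038	55182	L1PA2:L1PA5			no		LINE-mediated rearrangement	C>T@129544095	yes	471-bp identity block between flanking L1 copies; no junction signature printed
P18	DEL	1	129566786	129578227	11441		A		no		NHEJ or MMBIR	A>G@129578335	yes	
P19	DEL	1	129612189	129613535	1346		A		no		NHEJ or MMBIR	insA@129613597-129613598	yes	
P20	DEL	1	129658427	129664812	6390		AGTACA		no		NHEJ or MMBIR		yes	printed length 6390 != coordinate difference 6385
P21	DEL	1	129710417	NA	NA				no				no	left breakpoint localized to 129710417-129711135; right end beyond target region (129837710+)
P22	DEL-NML-DEL	1	129746506	129775772	29266		GCACACCCAAAACTCCCTGT		no		NHEJ or MMBIR		yes	row interleaves two junctions; split per narrative (curator interpretation); complex event attributed to FoSTeS/MMBIR
P22	DEL-NML-DEL	2	129776069	129779042	2973			TAAACCCAAAACAGC	no	random	NHEJ or MMBIR		yes	second junction of DEL-NML-DEL event
P23	DEL	1	129778345	129782637	4292			TA	no	random	NHEJ		yes	
P24	DEL	1	129778345	129782637	4292			TA	no	random	NHEJ		yes	
P25	DEL	1	129778271	129813338	35067				yes		NHEJ	C>G@129778200;T>C@129813347	yes	
P26	DEL	1	129816374	129833601	17227		CAAA		no		NHEJ or MMBIR		yes	upstream breakpoint inside an L3 fragment (129816155-129816735); recurrent possible founder
P27	DEL	1	129816374	129833601	17227		CAAA		no		NHEJ or MMBIR		yes	upstream breakpoint inside an L3 fragment (129816155-129816735); recurrent possible founder
P28	DEL	1	129816374	129833601	17227		CAAA		no		NHEJ or MMBIR		yes	upstream breakpoint inside an L3 fragment (129816155-129816735); recurrent possible founder
P29	DEL	1	129833559	129833615	56				no				yes	56-bp intra-exonic deletion (exon 63); below CNV size floor, treated as small variant
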