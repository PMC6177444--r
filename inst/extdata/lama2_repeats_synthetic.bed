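chr6	129488000	129488857	L1PA2	0	+	LINE
chr6	129543500	129544500	L1PA5	0	+	LINE
chr6	129816154	129816735	L3	0	+	LINE
chr6	129355000	129355900	L1MB7	0	+	LINE
chr6	129548200	129548800	AluY	0	+	SINE
chr6	129379000	129379600	L2	0	+	LINE
chr6	129423200	129423900	L1PA7	0	+	LINE
chr6	129578000	129578600	MIR	0	+	SINE
chr6	129746200	129746900	AluSx	0	+	SINE
chr6	129664500	129665200	L1ME3	0	+	LINE
chr6	129300000	129300600	AluJb	0	+	SINE
chr6	129500000	129500900	L1MA4	0	+	LINE
chr6	129700000	129700500	MLT1	0	+	LTR
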