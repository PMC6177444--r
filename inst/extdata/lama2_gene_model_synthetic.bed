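chr6	129206285	129206438	1	153
chr6	129215968	129216058	2	90
chr6	129225652	129225895	3	243
chr6	129235335	129235485	4	150
chr6	129245019	129245127	5	108
chr6	129254702	129254864	6	162
chr6	129264386	129264629	7	243
chr6	129274069	129274279	8	210
chr6	129283753	129283843	9	90
chr6	129293436	129293556	10	120
chr6	129303120	129303300	11	180
chr6	129312803	129312863	12	60
chr6	129322487	129322730	13	243
chr6	129332170	129332260	14	90
chr6	129341853	129342096	15	243
chr6	129351537	129351717	16	180
chr6	129361220	129361370	17	150
chr6	129370904	129371114	18	210
chr6	129380587	129380737	19	150
chr6	129390271	129390469	20	198
chr6	129399954	129400125	21	171
chr6	129409638	129409881	22	243
chr6	129419321	129419531	23	210
chr6	129429005	129429125	24	120
chr6	129438688	129438886	25	198
chr6	129448372	129448552	26	180
chr6	129458055	129458208	27	153
chr6	129467738	129467837	28	99
chr6	129477422	129477665	29	243
chr6	129487105	129487213	30	108
chr6	129496789	129496987	31	198
chr6	129506472	129506592	32	120
chr6	129516156	129516276	33	120
chr6	129525839	129526037	34	198
chr6	129535523	129535598	35	75
chr6	129545206	129545281	36	75
chr6	129554890	129554998	37	108
chr6	129564573	129564681	38	108
chr6	129574257	129574386	39	129
chr6	129583940	129584060	40	120
chr6	129593623	129593722	41	99
chr6	129603307	129603436	42	129
chr6	129612990	129613089	43	99
chr6	129622674	129622872	44	198
chr6	129632357	129632519	45	162
chr6	129642041	129642191	46	150
chr6	129651724	129651859	47	135
chr6	129661408	129661570	48	162
chr6	129671091	129671301	49	210
chr6	129680775	129680850	50	75
chr6	129690458	129690668	51	210
chr6	129700142	129700202	52	60
chr6	129709825	129709975	53	150
chr6	129719508	129719598	54	90
chr6	129729192	129729267	55	75
chr6	129738875	129739046	56	171
chr6	129748559	129748709	57	150
chr6	129758242	129758422	58	180
chr6	129767926	129768169	59	243
chr6	129777609	129777699	60	90
chr6	129787293	129787392	61	99
chr6	129796976	129797156	62	180
chr6	129806660	129806903	63	243
chr6	129816343	129816523	64	180
chr6	129826027	129826162	65	135
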