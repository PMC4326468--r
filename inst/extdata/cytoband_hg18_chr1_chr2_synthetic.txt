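chr1	0	2300000	p36.33	gneg
chr1	2300000	5300000	p36.32	gpos25
chr1	5300000	6300000	p36.31	gneg
chr1	6300000	7100000	p36.23	gpos25
chr1	7100000	8400000	p36.22	gneg
chr1	8400000	9200000	p36.21	gpos50
chr1	9200000	12600000	p36.13	gneg
chr1	12600000	14500000	p36.12	gpos25
chr1	14500000	16100000	p36.11	gneg
chr1	16100000	21800000	p35	gpos50
chr1	21800000	26500000	p34.3	gneg
chr1	26500000	29300000	p34.2	gpos25
chr1	29300000	32700000	p34.1	gneg
chr1	32700000	34600000	p33	gpos50
chr1	34600000	39600000	p32.3	gneg
chr1	39600000	43700000	p32.2	gpos25
chr1	43700000	46300000	p32.1	gneg
chr1	46300000	50200000	p31.3	gpos50
chr1	50200000	55600000	p31.2	gneg
chr1	55600000	68500000	p31.1	gpos100
chr1	68500000	69800000	p22.3	gneg
chr1	69800000	74500000	p22.2	gpos50
chr1	74500000	84400000	p22.1	gneg
chr1	84400000	94200000	p21	gpos100
chr1	94200000	99400000	p13.3	gneg
chr1	99400000	102000000	p13.2	gpos50
chr1	102000000	107000000	p13.1	gneg
chr1	107000000	111600000	p12	gpos50
chr1	111600000	115900000	p11.2	gneg
chr1	115900000	121100000	p11.1	acen
chr1	121100000	124300000	q11	acen
chr1	124300000	128000000	q12	gvar
chr1	128000000	142400000	q21.1	gneg
chr1	142400000	148000000	q21.2	gpos50
chr1	148000000	153400000	q21.3	gneg
chr1	153400000	154500000	q22	gpos50
chr1	154500000	156500000	q23.1	gneg
chr1	156500000	159100000	q23.2	gpos50
chr1	159100000	163500000	q23.3	gneg
chr1	163500000	165500000	q24.1	gpos50
chr1	165500000	167100000	q24.2	gneg
chr1	167100000	170900000	q24.3	gpos75
chr1	170900000	172900000	q25.1	gneg
chr1	172900000	176000000	q25.2	gpos50
chr1	176000000	185800000	q25.3	gneg
chr1	185800000	190800000	q31.1	gpos100
chr1	190800000	193800000	q31.2	gneg
chr1	193800000	198700000	q31.3	gpos100
chr1	198700000	207100000	q32.1	gneg
chr1	207100000	211300000	q32.2	gpos25
chr1	211300000	214400000	q32.3	gneg
chr1	214400000	223900000	q41	gpos100
chr1	223900000	224400000	q42.11	gneg
chr1	224400000	226900000	q42.12	gpos25
chr1	226900000	230500000	q42.13	gneg
chr1	230500000	234600000	q42.2	gpos50
chr1	234600000	236600000	q42.3	gneg
chr1	236600000	241700000	q43	gpos75
chr1	241700000	247249719	q44	gneg
chr2	0	4400000	p25.3	gneg
chr2	4400000	6900000	p25.2	gpos50
chr2	6900000	12000000	p25.1	gneg
chr2	12000000	16500000	p24.3	gpos75
chr2	16500000	19000000	p24.2	gneg
chr2	19000000	23800000	p24.1	gpos75
chr2	23800000	27700000	p23.3	gneg
chr2	27700000	29800000	p23.2	gpos25
chr2	29800000	31800000	p23.1	gneg
chr2	31800000	36300000	p22.3	gpos75
chr2	36300000	38300000	p22.2	gneg
chr2	38300000	41500000	p22.1	gpos50
chr2	41500000	47500000	p21	gneg
chr2	47500000	52600000	p16.3	gpos100
chr2	52600000	54700000	p16.2	gneg
chr2	54700000	61000000	p16.1	gpos100
chr2	61000000	63900000	p15	gneg
chr2	63900000	68400000	p14	gpos50
chr2	68400000	74800000	p13	gneg
chr2	74800000	83300000	p12	gpos100
chr2	83300000	91800000	p11.2	gneg
chr2	91800000	93300000	p11.1	acen
chr2	93300000	95700000	q11.1	acen
chr2	95700000	102100000	q11.2	gneg
chr2	102100000	108700000	q12	gpos50
chr2	108700000	112800000	q13	gneg
chr2	112800000	118100000	q14.1	gpos50
chr2	118100000	121900000	q14.2	gneg
chr2	121900000	129900000	q14.3	gpos50
chr2	129900000	132500000	q21.1	gneg
chr2	132500000	135100000	q21.2	gpos25
chr2	135100000	136800000	q21.3	gneg
chr2	136800000	142200000	q22.1	gpos100
chr2	142200000	144100000	q22.2	gneg
chr2	144100000	148700000	q22.3	gpos100
chr2	148700000	149900000	q23.1	gneg
chr2	149900000	150500000	q23.2	gpos25
chr2	150500000	154900000	q23.3	gneg
chr2	154900000	159800000	q24.1	gpos75
chr2	159800000	163700000	q24.2	gneg
chr2	163700000	169700000	q24.3	gpos75
chr2	169700000	178000000	q31.1	gneg
chr2	178000000	180500000	q31.2	gpos50
chr2	180500000	183000000	q31.3	gneg
chr2	183000000	189400000	q32.1	gpos75
chr2	189400000	191900000	q32.2	gneg
chr2	191900000	197400000	q32.3	gpos75
chr2	197400000	203300000	q33.1	gneg
chr2	203300000	204900000	q33.2	gpos50
chr2	204900000	209000000	q33.3	gneg
chr2	209000000	215300000	q34	gpos100
chr2	215300000	221500000	q35	gneg
chr2	221500000	225200000	q36.1	gpos75
chr2	225200000	226100000	q36.2	gneg
chr2	226100000	230700000	q36.3	gpos100
chr2	230700000	234700000	q37.1	gneg
chr2	234700000	236400000	q37.2	gpos50
chr2	236400000	242951149	q37.3	gneg
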