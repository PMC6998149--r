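taxon_id	DON1_donor	DON2_donor	P01_W-2	P01_D0	P01_W2	P01_W6	P02_W-2	P02_D0	P02_W2	P02_W6	P03_W-2	P03_D0	P03_W2	P03_W6	P04_W-2	P04_D0	P04_W2	P04_W6	taxonomy
OTU001	0	26	0	0	0	0	52	22	15	29	53	42	46	33	0	0	2	0	k__Bacteria;p__P2;c__C2;o__O2;f__F2;g__G001
OTU002	1	8	34	20	18	6	64	59	27	23	37	17	51	27	2	0	0	0	k__Bacteria;p__P3;c__C3;o__O3;f__F3;g__G002
OTU003	76	4	0	0	33	25	0	0	4	3	37	13	28	27	19	53	43	41	k__Bacteria;p__P4;c__C4;o__O4;f__F4;g__G003
OTU004	1	0	1	0	0	0	8	8	9	10	83	163	126	154	0	0	0	0	k__Bacteria;p__P5;c__C5;o__O5;f__F5;g__G004
OTU005	13	13	86	57	34	46	49	33	14	10	0	0	0	0	0	0	0	0	k__Bacteria;p__P6;c__C6;o__O6;f__F6;g__G005
OTU006	38	18	89	118	59	33	0	0	6	11	0	0	0	0	25	9	35	26	k__Bacteria;p__P7;c__C7;o__O7;f__F7;g__G006
OTU007	3	149	7	4	7	4	7	8	55	51	2	5	1	2	38	51	44	33	k__Bacteria;p__P1;c__C8;o__O8;f__F8;g__G007
OTU008	0	1	0	1	0	0	0	0	1	1	25	18	22	52	7	3	1	6	k__Bacteria;p__P2;c__C9;o__O9;f__F9;g__G008
OTU009	27	6	151	157	94	59	5	1	3	4	4	2	3	7	96	22	35	41	k__Bacteria;p__P3;c__C10;o__O10;f__F10;g__G009
OTU010	12	37	138	139	50	41	9	6	19	21	167	122	133	78	3	7	5	4	k__Bacteria;p__P4;c__C11;o__O11;f__F11;g__G010
OTU011	12	31	1	0	5	9	47	45	40	35	9	10	15	14	108	159	157	281	k__Bacteria;p__P5;c__C12;o__O12;f__F12;g__G011
OTU012	0	4	6	5	0	1	4	1	2	6	152	81	53	106	21	7	10	7	k__Bacteria;p__P6;c__C13;o__O13;f__F13;g__G012
OTU013	0	4	0	0	0	0	37	59	31	70	0	0	0	0	7	9	16	5	k__Bacteria;p__P7;c__C1;o__O14;f__F14;g__G013
OTU014	3	0	18	29	8	4	35	20	22	36	51	110	64	160	10	5	3	3	k__Bacteria;p__P1;c__C2;o__O15;f__F15;g__G014
OTU015	3	7	22	30	40	20	11	10	14	9	1	4	2	4	109	43	51	102	k__Bacteria;p__P2;c__C3;o__O16;f__F16;g__G015
OTU016	25	15	0	0	41	72	26	15	72	28	1	2	0	1	19	6	6	11	k__Bacteria;p__P3;c__C4;o__O17;f__F17;g__G016
OTU017	64	3	1	0	37	18	179	99	65	129	0	0	0	0	0	2	1	0	k__Bacteria;p__P4;c__C5;o__O1;f__F18;g__G017
OTU018	14	13	3	3	7	3	0	0	2	10	21	62	27	34	59	51	26	23	k__Bacteria;p__P5;c__C6;o__O2;f__F19;g__G018
OTU019	0	301	48	25	9	14	107	192	226	197	36	33	32	21	33	33	21	30	k__Bacteria;p__P6;c__C7;o__O3;f__F20;g__G019
OTU020	5	17	1	2	1	4	14	8	31	11	0	0	0	3	55	49	28	46	k__Bacteria;p__P7;c__C8;o__O4;f__F21;g__G020
OTU021	82	11	40	40	72	36	38	34	20	24	0	0	0	0	4	4	7	6	k__Bacteria;p__P1;c__C9;o__O5;f__F22;g__G021
OTU022	105	21	8	2	154	142	0	0	3	10	20	22	6	6	2	1	2	4	k__Bacteria;p__P2;c__C10;o__O6;f__F23;g__G022
OTU023	21	1	2	0	11	21	0	0	2	1	0	0	0	0	55	129	137	29	k__Bacteria;p__P3;c__C11;o__O7;f__F24;g__G023
OTU024	0	51	0	0	2	0	46	35	61	36	3	4	1	1	2	0	0	0	k__Bacteria;p__P4;c__C12;o__O8;f__F25;g__G024
OTU025	105	0	0	0	82	83	0	0	0	0	1	3	0	0	0	0	0	0	k__Bacteria;p__P5;c__C13;o__O9;f__F26;g__G025
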