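# Probe-labeling sites of the Ub vinyl-pentynyl-sulfone probe in HEK 293T
# lysate, transcribed by hand from the source publication's printed site
# table. One row per (protein, site). Columns:
#   protein          short protein name as printed
#   class            USP | OTU | UCH | JOS (DUB classes) or Other (non-DUB)
#   site             1-based Cys residue number
#   high_confidence  TRUE if printed in bold (seen in >1 biological replicate)
#   non_catalytic    TRUE if starred (non-active-site Cys of a DUB)
#   catalytic_of_non_dub  TRUE if daggered (catalytic residue of a non-DUB)
protein	class	site	high_confidence	non_catalytic	catalytic_of_non_dub
UBP1	USP	90	TRUE	FALSE	FALSE
UBP3	USP	168	TRUE	FALSE	FALSE
UBP5	USP	219	FALSE	TRUE	FALSE
UBP5	USP	335	TRUE	FALSE	FALSE
UBP5	USP	471	TRUE	TRUE	FALSE
UBP7	USP	90	FALSE	TRUE	FALSE
UBP7	USP	121	FALSE	TRUE	FALSE
UBP7	USP	223	TRUE	FALSE	FALSE
UBP7	USP	315	TRUE	TRUE	FALSE
UBP8	USP	786	TRUE	FALSE	FALSE
UBP8	USP	809	FALSE	TRUE	FALSE
USP9X	USP	1566	TRUE	FALSE	FALSE
UBP10	USP	424	TRUE	FALSE	FALSE
UBP10	USP	436	TRUE	TRUE	FALSE
UBP10	USP	697	FALSE	TRUE	FALSE
UBP12	USP	48	TRUE	FALSE	FALSE
UBP13	USP	345	FALSE	FALSE	FALSE
UBP14	USP	105	FALSE	TRUE	FALSE
UBP14	USP	114	TRUE	FALSE	FALSE
UBP14	USP	122	FALSE	TRUE	FALSE
UBP14	USP	203	TRUE	TRUE	FALSE
UBP14	USP	257	TRUE	TRUE	FALSE
UBP14	USP	359	TRUE	TRUE	FALSE
UBP14	USP	415	FALSE	TRUE	FALSE
UBP15	USP	289	FALSE	TRUE	FALSE
UBP15	USP	298	TRUE	FALSE	FALSE
UBP16	USP	205	TRUE	FALSE	FALSE
UBP19	USP	506	TRUE	FALSE	FALSE
UBP21	USP	221	FALSE	FALSE	FALSE
UBP22	USP	171	TRUE	TRUE	FALSE
UBP22	USP	185	TRUE	FALSE	FALSE
UBP24	USP	1698	TRUE	FALSE	FALSE
UBP25	USP	178	TRUE	FALSE	FALSE
UBP27	USP	87	TRUE	FALSE	FALSE
UBP27	USP	91	TRUE	TRUE	FALSE
UBP28	USP	171	TRUE	FALSE	FALSE
UBP30	USP	77	TRUE	FALSE	FALSE
UBP33	USP	194	TRUE	FALSE	FALSE
UBP34	USP	1903	TRUE	FALSE	FALSE
UBP35	USP	450	TRUE	FALSE	FALSE
UBP36	USP	131	FALSE	FALSE	FALSE
UBP37	USP	350	TRUE	FALSE	FALSE
UBP38	USP	454	TRUE	FALSE	FALSE
UBP40	USP	50	TRUE	FALSE	FALSE
UBP42	USP	120	TRUE	FALSE	FALSE
UBP45	USP	199	TRUE	FALSE	FALSE
UBP47	USP	197	TRUE	FALSE	FALSE
UBP54	USP	42	FALSE	FALSE	FALSE
OTU1	OTU	160	TRUE	FALSE	FALSE
OTU6B	OTU	158	TRUE	FALSE	FALSE
OTU6B	OTU	172	TRUE	TRUE	FALSE
OTU7A	OTU	210	TRUE	FALSE	FALSE
OTUB1	OTU	91	TRUE	FALSE	FALSE
OTUB2	OTU	51	TRUE	FALSE	FALSE
OTUD3	OTU	76	TRUE	FALSE	FALSE
OTUD4	OTU	45	TRUE	FALSE	FALSE
OTUD5	OTU	224	TRUE	FALSE	FALSE
ZRAN1	OTU	443	TRUE	FALSE	FALSE
BAP1	UCH	91	TRUE	FALSE	FALSE
BAP1	UCH	103	FALSE	TRUE	FALSE
UCHL1	UCH	47	TRUE	TRUE	FALSE
UCHL1	UCH	90	TRUE	FALSE	FALSE
UCHL1	UCH	152	TRUE	TRUE	FALSE
UCHL1	UCH	220	TRUE	TRUE	FALSE
UCHL3	UCH	50	TRUE	TRUE	FALSE
UCHL3	UCH	95	TRUE	FALSE	FALSE
UCHL5	UCH	9	TRUE	TRUE	FALSE
UCHL5	UCH	88	TRUE	FALSE	FALSE
UCHL5	UCH	100	TRUE	TRUE	FALSE
ATX3	JOS	14	TRUE	FALSE	FALSE
ATX3	JOS	18	TRUE	TRUE	FALSE
JOS1	JOS	36	TRUE	FALSE	FALSE
JOS2	JOS	24	TRUE	FALSE	FALSE
1433T	Other	134	FALSE	FALSE	FALSE
A6NLJ7	Other	9	FALSE	FALSE	FALSE
ADRM1	Other	357	FALSE	FALSE	FALSE
ALDOA	Other	339	TRUE	FALSE	FALSE
AUP1	Other	391	FALSE	FALSE	FALSE
BOLA2	Other	31	FALSE	FALSE	FALSE
CATB	Other	319	FALSE	FALSE	FALSE
CH60	Other	442	TRUE	FALSE	FALSE
CLIC4	Other	35	FALSE	FALSE	FALSE
DCAF7	Other	256	TRUE	FALSE	FALSE
DDX55	Other	437	TRUE	FALSE	FALSE
DFFA	Other	165	FALSE	FALSE	FALSE
EF1A1	Other	411	TRUE	FALSE	FALSE
EF2	Other	41	FALSE	FALSE	FALSE
EIF3I	Other	76	TRUE	FALSE	FALSE
FETUA	Other	132	TRUE	FALSE	FALSE
HECD1	Other	2579	TRUE	FALSE	FALSE
IF5A1	Other	22	TRUE	FALSE	FALSE
IF5A1	Other	73	FALSE	FALSE	FALSE
IMDH2	Other	331	TRUE	FALSE	FALSE
KLH28	Other	189	FALSE	FALSE	FALSE
KPYM	Other	423	FALSE	FALSE	FALSE
KPYM	Other	424	TRUE	FALSE	FALSE
LDH6A	Other	163	TRUE	FALSE	FALSE
LDHA	Other	35	FALSE	FALSE	FALSE
LDHB	Other	36	FALSE	FALSE	FALSE
LDHB	Other	294	TRUE	FALSE	FALSE
MIF	Other	60	FALSE	FALSE	FALSE
MIF	Other	81	TRUE	FALSE	FALSE
NDK8	Other	94	FALSE	FALSE	FALSE
PAIRB	Other	11	FALSE	FALSE	FALSE
PAL4A	Other	62	TRUE	FALSE	FALSE
PCBP1	Other	54	TRUE	FALSE	FALSE
PPIA	Other	115	TRUE	FALSE	FALSE
PROF1	Other	128	TRUE	FALSE	FALSE
Q5HYB6	Other	154	TRUE	FALSE	FALSE
RCC2	Other	428	TRUE	FALSE	FALSE
RHOA	Other	16	TRUE	FALSE	FALSE
RL10L	Other	105	FALSE	FALSE	FALSE
RL12	Other	141	TRUE	FALSE	FALSE
RL14	Other	42	FALSE	FALSE	FALSE
RL23	Other	28	TRUE	FALSE	FALSE
RL9	Other	134	TRUE	FALSE	FALSE
RS20	Other	70	TRUE	FALSE	FALSE
RS27L	Other	77	TRUE	FALSE	FALSE
RS28	Other	27	TRUE	FALSE	FALSE
RS3	Other	134	FALSE	FALSE	FALSE
RS6	Other	12	FALSE	FALSE	FALSE
RSSA	Other	148	FALSE	FALSE	FALSE
SAP	Other	409	FALSE	FALSE	FALSE
SAP	Other	476	FALSE	FALSE	FALSE
SENP8	Other	163	TRUE	FALSE	TRUE
SERA	Other	369	TRUE	FALSE	FALSE
SPEE	Other	71	TRUE	FALSE	FALSE
SQSTM	Other	113	FALSE	FALSE	FALSE
TBA1A	Other	25	TRUE	FALSE	FALSE
TBA1A	Other	129	TRUE	FALSE	FALSE
TBA1A	Other	295	TRUE	FALSE	FALSE
TBA1A	Other	347	FALSE	FALSE	FALSE
TBA1A	Other	376	TRUE	FALSE	FALSE
TBA1B	Other	347	TRUE	FALSE	FALSE
TBB2A	Other	12	TRUE	FALSE	FALSE
TBB2A	Other	239	TRUE	FALSE	FALSE
TBB2A	Other	303	TRUE	FALSE	FALSE
TBB2A	Other	354	TRUE	FALSE	FALSE
TBB4A	Other	127	FALSE	FALSE	FALSE
TBC15	Other	24	TRUE	FALSE	FALSE
TEBP	Other	40	TRUE	FALSE	FALSE
THIO	Other	32	TRUE	FALSE	FALSE
THIO	Other	35	FALSE	FALSE	FALSE
THIO	Other	73	TRUE	FALSE	FALSE
UBE3C	Other	1051	TRUE	FALSE	TRUE
ZNFX1	Other	1860	TRUE	FALSE	FALSE
ZUFSP	Other	360	TRUE	FALSE	FALSE
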