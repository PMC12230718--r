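# IRE apical-loop motif registry.
# One row per loop pattern. Columns (tab-separated):
#   motif_id  family  version  n8  loop_pattern  cross_pair  extension
# loop_pattern covers positions N14-N19 in IUPAC code; cross_pair is the
# N14-N18 cross-loop pair; extension, when present, gives N19i-N19ii.
motif_id	family	version	n8	loop_pattern	cross_pair	extension
1	1	legacy_v1_2	C	CAGUGN	C-G	-
2	2	legacy_v1_2	C	CAGAGH	C-G	-
3	3	legacy_v1_2	C	CUGUGY	C-G	-
4	4	legacy_v1_2	C	CCGUGH	C-G	-
5	5	legacy_v1_2	C	CCGAGA	C-G	-
6	6	legacy_v1_2	C	CUUAGC	C-G	-
7	7	legacy_v1_2	C	CAAUGC	C-G	-
8	8	legacy_v1_2	C	CAGGGN	C-G	-
9a	9	legacy_v1_2	C	UAGUAY	U-A	-
9b	9	new_v3	C	UAGUAR	U-A	-
10	10	legacy_v1_2	C	UAGGAU	U-A	-
11	11	legacy_v1_2	C	UAGAAY	U-A	-
12	12	legacy_v1_2	C	UAGCAG	U-A	-
13	13	legacy_v1_2	C	GAGUCR	G-C	-
14	14	legacy_v1_2	C	GAGCCR	G-C	-
15	15	legacy_v1_2	C	GAGAGK	G-G	-
16	16	legacy_v1_2	C	GGGAGN	G-G	-
17	17	legacy_v1_2	C	GAGUGW	G-G	-
18	18	legacy_v1_2	G	CAGUGA	C-G	-
19	19	new_v3	C	AAGUUN	A-U	-
20	20	new_v3	U	CAGUGN	C-G	-
21	21	new_v3	U	CAGAGN	C-G	-
22	22	new_v3	U	CAGUGN	C-G	CA
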