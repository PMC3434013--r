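# Best-match cluster sizes reported in the worked benchmark: for each
# known complex, the size of the best-matching predicted cluster and the
# number of shared members, for clustering on the static network and on
# the dynamic (TSN) network.
# known_id	network	pc_size	overlap
DIG	static	4	3
DIG	dynamic	3	3
AP3	static	3	3
AP3	dynamic	4	4
SAS	static	11	3
SAS	dynamic	3	3
MRX	static	4	1
MRX	dynamic	3	3
PREFOLDIN	static	11	5
PREFOLDIN	dynamic	6	5
AP1	static	6	4
AP1	dynamic	5	4
DASH	static	36	7
DASH	dynamic	7	7
FBP	static	4	3
FBP	dynamic	8	7
ARGR	static	6	4
ARGR	dynamic	3	3
RETROMER	static	5	3
RETROMER	dynamic	4	3
POLA	static	12	3
POLA	dynamic	3	3
SEC62	static	129	1
SEC62	dynamic	3	3
SRB	static	54	20
SRB	dynamic	19	18
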