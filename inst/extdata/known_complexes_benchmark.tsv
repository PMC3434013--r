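# Gold-standard yeast complexes used in the worked benchmark examples
# (id <TAB> semicolon-separated members)
DIG	DIG1;DIG2;STE12
AP3	APL5;APL6;APM3;APS3
SAS	SAS2;SAS4;SAS5
MRX	MRE11;RAD50;XRS2
PREFOLDIN	GIM3;GIM4;GIM5;PAC10;PFD1;YKE2
AP1	APL2;APL4;APM1;APS1
DASH	ASK1;DAD1;DAD2;DAD3;DAD4;DAM1;DUO1;SPC19;SPC34
FBP	RMD5;GID7;GID8;VID24;VID28;VID30;FYV10;YDL176W
ARGR	ARG80;ARG81;ARG82;MCM1
RETROMER	PEP8;VPS29;VPS35
POLA	POL1;POL12;PRI1;PRI2
SEC62	SEC62;SEC63;SEC66;SEC72
SRB	SSN3;SSN8;SRB8;SSN2;CSE2;GAL11;MED1;MED11;MED2;MED4;MED6;MED7;MED8;NUT1;NUT2;PGD1;RGR1;ROX3;SIN4;SRB2;SRB4;SRB5;SRB6;SRB7;SOH1
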