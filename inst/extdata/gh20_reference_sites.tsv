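enzyme	accession	subunit	chain	auth_index	label	note
SpHex	1HP5	.	A	162	cons_arg	.
SpHex	1HP5	.	A	444	cons_acid	Glu
SpHex	1HP5	.	A	214	remote_key	Val
ScHex	4C7G	.	A	191	cons_arg	.
ScHex	4C7G	.	A	473	cons_acid	Glu
ScHex	4C7G	.	A	243	remote_key	Val
NahA	3RCN	.	A	146	cons_arg	.
NahA	3RCN	.	A	456	cons_acid	Glu
NahA	3RCN	.	A	196	remote_key	Arg
Bf3009	4PYS	.	A	153	cons_arg	.
Bf3009	4PYS	.	A	450	cons_acid	Asp
Bf3009	4PYS	.	A	209	remote_key	Gln
Hex1T	3GH5	.	A	170	cons_arg	.
Hex1T	3GH5	.	A	443	cons_acid	Glu
Hex1T	3GH5	.	A	222	remote_key	Val
SmCHB	1QBB	.	A	349	cons_arg	.
SmCHB	1QBB	.	A	739	cons_acid	Glu
SmCHB	1QBB	.	A	413	remote_key	Tyr
SmCHB	1QBB	.	A	399	remote_key	Arg
LnbB	4JAW	.	A	190	cons_arg	Gln substitute; acts in subsite -2
LnbB	4JAW	.	A	467	cons_acid	Asp
LnbB	4JAW	.	A	574	remote_key	Leu; lectin domain
HexA	2GK1	alpha	.	178	cons_arg	subunit alpha; chain mapping needs the deposited file
HexA	2GK1	alpha	.	462	cons_acid	Glu
HexA	2GK1	alpha	.	548	remote_key	Ala; from subunit beta
HexA	2GK1	alpha	.	549	remote_key	Gly; from subunit beta
HexA	2GK1	beta	.	211	cons_arg	.
HexA	2GK1	beta	.	491	cons_acid	Glu
HexA	2GK1	beta	.	519	remote_key	Val; from subunit alpha
HexA	2GK1	beta	.	520	remote_key	Gly; from subunit alpha
HexB	1NP0	.	A	211	cons_arg	.
HexB	1NP0	.	A	491	cons_acid	Glu
HexB	1NP0	.	A	548	remote_key	Ala; from dimer partner
HexB	1NP0	.	A	549	remote_key	Gly; from dimer partner
OfHex1	3OZO	.	A	220	cons_arg	.
OfHex1	3OZO	.	A	526	cons_acid	Glu
OfHex1	3OZO	.	A	582	remote_key	Pro; from dimer partner
OfHex1	3OZO	.	A	583	remote_key	Glu; from dimer partner
GcnA	2EPN	.	A	95	cons_arg	.
GcnA	2EPN	.	A	376	cons_acid	Asp
GcnA	2EPN	.	A	627	remote_key	Thr; C-terminus of dimer partner
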