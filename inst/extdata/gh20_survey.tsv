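enzyme	organism	subunit	length_aa	pdb	chain	chains_analysis	domains	block_location	group	oligomer
SpHex	Streptomyces plicatus	.	506	1HP5	A	A	GH20b-GH20-alpha	19-494	monomeric	monomer
ScHex	Streptomyces coelicolor A3(2)	.	535	4C7G	A	A	GH20b-GH20-alpha	11-511	monomeric	monomer
Hex1T	Paenibacillus sp.	.	978	3GH5	A	A	GH20b-GH20-alpha-Lectin-CBD	15-493	monomeric	monomer
SmCHB	Serratia marcescens	.	885	1QBB	A	A	CHB_HEX-GH20b-GH20-alpha-CHB_HEX_C	215-814	monomeric	monomer
LnbB	Bifidobacterium bifidum	.	1112	4JAW	A	A,B	GH20b-GH20-alpha-Lectin-CBM32-Ig_like	34-515	monomeric	monomer
NahA	Arthrobacter aurescens	.	540	3RCN	A	A	GH20b-GH20-	5-506	monomeric	unknown
Bf3009	Bacteroides fragilis	.	518	4PYS	A	A,B	GH20b-GH20-alpha	21-498	monomeric	unknown
HexA	Homo sapiens	alpha	529	2GK1	A	A,B,C,D,E,F,G	GH20b-GH20-alpha	23-510	heterodimeric	heterodimer
HexA	Homo sapiens	beta	556	2GK1	B	A,B,C,D,E,F,G	GH20b-GH20-alpha	56-540	heterodimeric	heterodimer
HexB	Homo sapiens	.	556	1NP0	A	A,B	GH20b-GH20-alpha	56-540	homodimeric	homodimer
OfHex1	Ostrinia furnacalis	.	593	3OZO	A	A	GH20b-GH20-alpha	65-574	homodimeric	homodimer
GcnA	Streptococcus gordonii	.	627	2EPN	A	A,B	GH20b-GH20-alpha-DomainIII	2-414	homodimeric	homodimer
DspB	Aggregatibacter actinomycetemcomitans	.	361	1YHT	A	A	GH20	20-342	monomeric	monomer
StrH	Streptococcus pneumoniae	.	1312	3RPM	A	A,B	GH20-GH20-G5-G5	190-538,635-972	monomeric	monomer
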