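enzyme	subunit	loop2_start	loop2_end	remote_source	remote_start	remote_end	remote_label
SpHex	.	209	223	loop2	209	223	loop2
ScHex	.	238	252	loop2	238	252	loop2
NahA	.	193	219	loop2	193	219	loop2
Bf3009	.	200	214	loop2	200	214	loop2
Hex1T	.	217	231	loop2	217	231	loop2
SmCHB	.	396	425	loop2	396	425	loop2
LnbB	.	231	236	accompanying_domain	570	578	Lectin
HexA	alpha	225	235	partner_chain	543	552	beta_Cterm
HexA	beta	258	267	partner_chain	514	523	alpha_Cterm
HexB	.	258	267	partner_chain	514	523	dimer_Cterm
OfHex1	.	267	276	partner_chain	577	594	dimer_Cterm
GcnA	.	136	143	partner_chain	622	627	dimer_Cterm
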