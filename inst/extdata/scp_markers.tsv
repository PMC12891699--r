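marker_id	gene_symbol	profile_accessions	module	branch	required	weight
hemB	hemB	K01698	precursor	shared	TRUE	1
hemC	hemC	K01749	precursor	shared	TRUE	1
hemD	hemD	K01719	precursor	shared	TRUE	1
cysG	cysG	K02302	precursor	shared	TRUE	1
cbiA	cbiA	K02224	ring	anaerobic	TRUE	1
cbiD	cbiD	K02188	ring	anaerobic	TRUE	1
cbiF	cbiF	K02189	ring	anaerobic	TRUE	1
cbiH	cbiH	K03396	ring	anaerobic	TRUE	1
cbiL	cbiL	K03394	ring	anaerobic	TRUE	1
cobF	cobF	K05934	ring	aerobic	TRUE	1
cobG	cobG	K02229	ring	aerobic	TRUE	1
cobJ	cobJ	K02228	ring	aerobic	TRUE	1
cobM	cobM	K05936	ring	aerobic	TRUE	1
cobL	cobL	K00595	ring	aerobic	TRUE	1
cbiK	cbiK	K02190	chelation	anaerobic	TRUE	1
cbiX	cbiX	K03795	chelation	anaerobic	FALSE	1
cobN	cobN	K02230	chelation	aerobic	TRUE	1
cobS_chel	cobS	K09882	chelation	aerobic	FALSE	1
cobT_chel	cobT	K09883	chelation	aerobic	FALSE	1
cobA_btuR	cobA	K00798	adenosylation	shared	TRUE	1
cbiB	cbiB	K02227	loop	shared	TRUE	1
cobU	cobU	K02231	loop	shared	TRUE	1
cobS_loop	cobS	K02233	loop	shared	TRUE	1
cobC	cobC	K02226	loop	shared	TRUE	1
btuB	btuB	K16092	salvage	shared	FALSE	1
btuF	btuF	K06858	salvage	shared	FALSE	1
btuC	btuC	K06073	salvage	shared	FALSE	1
btuD	btuD	K06074	salvage	shared	FALSE	1
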