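name	species	group	residues	length_printed	net_charge_printed	length_text
Mcal mytilin 1	Mytilus californianus	mytilin	SCASRCKYRCRARRCRYYVSVRYGWFCYCRCLHC	34	9	
Mcal mytilin 2	Mytilus californianus	mytilin	SCASRCKSRCRARRCKYYVSVRYGWFCYCRCLRC	34	10	
Mcal mytilin 3	Mytilus californianus	mytilin	SCALLCKAHCRARRCGYYVSVFYHGRCYCRCLRC	34	7	
Mcal mytilin 4	Mytilus californianus	mytilin	SCASKCKAVCRRRRCAGYDWVLWGGHCFCKCSRC	34	7	
Mcal mytilin 5	Mytilus californianus	mytilin	SCASRCKYRCRRRRCRSYVAVRYCCRCLCKCRRC	34	13	
Mcal mytilin 6	Mytilus californianus	mytilin	SCIPRCKYICTRRRRCGYYAAIYYCHRCYCKCLSC	35	8	
Mcal PM	Mytilus californianus	pseudomytilin	SCRTRCRFKCFGRGCGAYFAAQYGDFCYCKCYRC	34	6	
Mcor mytilin 9	Mytilus coruscus	mytilin	SCASRCKSRCRARRCRYYVAVRYGWFCYCRCLRC	34	10	
Mgal mytilin L	Mytilus galloprovincialis	mytilin	YCPQSFRRICSSRCRGRGCQYYVAVCFPRRYYCKCLRC	38	9	39
Mgal mytilin M	Mytilus galloprovincialis	mytilin	SCASRCRSHCRARRCHYSKSVLVGRRCFCKCFLC	34	9	
Mgal PM 2	Mytilus galloprovincialis	pseudomytilin	SCRTRCRLKCFGRGCGAYFAAQRGPFCLCKCYRC	34	8	
Mgal PM 3	Mytilus galloprovincialis	pseudomytilin	SCRSRCRWKCFRRRCGAYFAAQRGPFCLCKCYRC	34	10	
Pcan mytilin 1	Perna canaliculus	mytilin	SCDRWCNTSCYNKGCRYYAASVSDGRCFCCCITC	34	2	
Pcan mytilin 2	Perna canaliculus	mytilin	NCARSCSSRCYHRNCKAYASVYRNETCYCCCIDC	34	3	
Pcan mytilin 3	Perna canaliculus	mytilin	SCATSCSSRCEYRKCEDYASAIRDGKCYCCCIKC	34	2	
Pcan mytilin 4	Perna canaliculus	mytilin	NCFSCPSTCARRGCRYFACATRLRKSYCCCFVC	33	6	
Pcan mytilin 5	Perna canaliculus	mytilin	SCFSCPRTCGARGCRYYACATRFGTSYCCCFKC	33	5	
Pcan mytilin 6	Perna canaliculus	mytilin	YCDLCRWYCSNKGCAYYLCGNKFGNNYCCCFKC	33	3	
Pcan mytilin 7	Perna canaliculus	mytilin	YCDRCREYCSNTGCGYYMCVRRIVDRRLKYYCCCFKC	37	5	
Pcan mytilin 8	Perna canaliculus	mytilin	GCGGCKYKCRRRGCRGYVCYKKRWLTICKCFRC	33	11	
Pvir mytilin 1	Perna viridis	mytilin	SCATSCSSRCYNKGCKYYAAAIRSGTCYCCCFKG	34	5	
Pvir mytilin 2	Perna viridis	mytilin	SCSSCPRTCGARGCRYYACATRLGTSYCCCFKC	33	5	
Pvir mytilin 3	Perna viridis	mytilin	DCDSNCNHRCYYRGCKAYASALNNGTCYCCCVDC	43	0	
Pvir mytilin 4	Perna viridis	mytilin	SCARCKDHCRNKGCGFYMCVLRYGTYYCCCFKC	33	5	
Pvir mytilin 5	Perna viridis	mytilin	NCERCKYYCSYKNCSQYMCVRHNANDYCCCFNC	33	2	
Pvir mytilin 6	Perna viridis	mytilin	ACDRCKAYCTIKGCGYYLCVHRFPSYYCCCFKC	33	4	
Pvir mytilin 7	Perna viridis	mytilin	SCYTCKRRCAARGCRYYLCVIRYYRVYCGCYRC	33	8	
Thir mytilin 1	Trichomya hirsuta	mytilin	SCSSICRYRCRRCRGFIWINIFGRCYCKCYGC	32	7	
Thir mytilin 2	Trichomya hirsuta	mytilin	SCASSCKSRCRSRGCKYFVSVRYRYHCYCKCLRC	34	9	
Thir mytilin 3	Trichomya hirsuta	mytilin	SCASRCKSRCRARRCKYYVSVRYGWFCYCKCLRC	34	10	
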