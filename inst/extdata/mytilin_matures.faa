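>Mcal_mytilin_1 Mytilus californianus mature peptide
SCASRCKYRCRARRCRYYVSVRYGWFCYCRCLHC
>Mcal_mytilin_2 Mytilus californianus mature peptide
SCASRCKSRCRARRCKYYVSVRYGWFCYCRCLRC
>Mcal_mytilin_3 Mytilus californianus mature peptide
SCALLCKAHCRARRCGYYVSVFYHGRCYCRCLRC
>Mcal_mytilin_4 Mytilus californianus mature peptide
SCASKCKAVCRRRRCAGYDWVLWGGHCFCKCSRC
>Mcal_mytilin_5 Mytilus californianus mature peptide
SCASRCKYRCRRRRCRSYVAVRYCCRCLCKCRRC
>Mcal_mytilin_6 Mytilus californianus mature peptide
SCIPRCKYICTRRRRCGYYAAIYYCHRCYCKCLSC
>Mcal_PM Mytilus californianus mature peptide
SCRTRCRFKCFGRGCGAYFAAQYGDFCYCKCYRC
>Mcor_mytilin_9 Mytilus coruscus mature peptide
SCASRCKSRCRARRCRYYVAVRYGWFCYCRCLRC
>Mgal_mytilin_L Mytilus galloprovincialis mature peptide
YCPQSFRRICSSRCRGRGCQYYVAVCFPRRYYCKCLRC
>Mgal_mytilin_M Mytilus galloprovincialis mature peptide
SCASRCRSHCRARRCHYSKSVLVGRRCFCKCFLC
>Mgal_PM_2 Mytilus galloprovincialis mature peptide
SCRTRCRLKCFGRGCGAYFAAQRGPFCLCKCYRC
>Mgal_PM_3 Mytilus galloprovincialis mature peptide
SCRSRCRWKCFRRRCGAYFAAQRGPFCLCKCYRC
>Pcan_mytilin_1 Perna canaliculus mature peptide
SCDRWCNTSCYNKGCRYYAASVSDGRCFCCCITC
>Pcan_mytilin_2 Perna canaliculus mature peptide
NCARSCSSRCYHRNCKAYASVYRNETCYCCCIDC
>Pcan_mytilin_3 Perna canaliculus mature peptide
SCATSCSSRCEYRKCEDYASAIRDGKCYCCCIKC
>Pcan_mytilin_4 Perna canaliculus mature peptide
NCFSCPSTCARRGCRYFACATRLRKSYCCCFVC
>Pcan_mytilin_5 Perna canaliculus mature peptide
SCFSCPRTCGARGCRYYACATRFGTSYCCCFKC
>Pcan_mytilin_6 Perna canaliculus mature peptide
YCDLCRWYCSNKGCAYYLCGNKFGNNYCCCFKC
>Pcan_mytilin_7 Perna canaliculus mature peptide
YCDRCREYCSNTGCGYYMCVRRIVDRRLKYYCCCFKC
>Pcan_mytilin_8 Perna canaliculus mature peptide
GCGGCKYKCRRRGCRGYVCYKKRWLTICKCFRC
>Pvir_mytilin_1 Perna viridis mature peptide
SCATSCSSRCYNKGCKYYAAAIRSGTCYCCCFKG
>Pvir_mytilin_2 Perna viridis mature peptide
SCSSCPRTCGARGCRYYACATRLGTSYCCCFKC
>Pvir_mytilin_3 Perna viridis mature peptide
DCDSNCNHRCYYRGCKAYASALNNGTCYCCCVDC
>Pvir_mytilin_4 Perna viridis mature peptide
SCARCKDHCRNKGCGFYMCVLRYGTYYCCCFKC
>Pvir_mytilin_5 Perna viridis mature peptide
NCERCKYYCSYKNCSQYMCVRHNANDYCCCFNC
>Pvir_mytilin_6 Perna viridis mature peptide
ACDRCKAYCTIKGCGYYLCVHRFPSYYCCCFKC
>Pvir_mytilin_7 Perna viridis mature peptide
SCYTCKRRCAARGCRYYLCVIRYYRVYCGCYRC
>Thir_mytilin_1 Trichomya hirsuta mature peptide
SCSSICRYRCRRCRGFIWINIFGRCYCKCYGC
>Thir_mytilin_2 Trichomya hirsuta mature peptide
SCASSCKSRCRSRGCKYFVSVRYRYHCYCKCLRC
>Thir_mytilin_3 Trichomya hirsuta mature peptide
SCASRCKSRCRARRCKYYVSVRYGWFCYCKCLRC
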