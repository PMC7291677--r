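wbgene	uniprot	entrez
WBGene00000001	A0A000W001	171590
WBGene00000002	A0A000W002	171591
WBGene00000003	A0A000W003	171592
WBGene00000004	A0A000W004	171593
WBGene00000005	A0A000W005	171594
WBGene00000006	A0A000W006	171595
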