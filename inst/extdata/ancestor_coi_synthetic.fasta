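>ancestor_synthetic|none
TTAATGTAATCTACCTTTTACCAGTGAAGGAATTATTCAATGTTCCTTTGGAATAAATAA
ACAGTATGTGTTGGATATTTGAACTACTGATTAACATAATAGAAAAATAGTAAATACCGT
TTCTCAAAAGATTGTAGTACGGATCTCATGAGGCTTCTGATATAAAATGATCCTAAAGTA
TGTAAATCCTTTAGATATCGGTACGAATATTAGAATTGTATTTAATATACCCTATATATG
AATTATTTCTTGTTGAATTCAACAATAATTTAAAAAGTACTCGAATAGTATAACACGTTT
CTGTACAATAACTAAACATATTCTTAAAATCGTGTCGAAGTCTTAGTGCTCATAAAACGT
AAGAAGATCAAACTAGATTGTACTTTAGGGCAGTGTATTTAATCTGTACTCGTATTCGAA
ACAATACTAAAAAGAGTCCCGAGTCGTAAGATACCTTAAAGGAAGCGTGTCTTATTCATA
GATAATGACAAACACGATAACATATCAAAAGGAGATACAGAATACCCTGATCGTTCAGTG
TTGACTGAAACTTTCGA
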