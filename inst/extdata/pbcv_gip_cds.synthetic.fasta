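>PbcvMT325GIP1;1
ACTAAGACTCCATCTGTTGGTATTTTCGTTAGAACTGCTGAAACTTCTGCTTTCTGGCTTTGTGGTCTTGTTATTGGTTA
CGCTGATGCTAACGGTTCTCAAGGTAGAACTTTCGGTCTTAGAACTAAGCTTTTCGGTTCTACTTTCGTTTTCGTTTCTA
CTTTCTTCGGTCATTGTCCAAAGAACACTAACTACGAAGGTTCTCATCATCAAGCTACTGGTAACGGTGCTCTTGGTGTT
AACCCAGCTCCAACTACTGGTGAAAAGATGGCTCTTAGAACTACTATGCTTGAATGGATTGGTTTCTGGGCTGCTCAAAA
GTGGGCTAGAATTCCAACTTCTACTTCTGATGGTAAGGGTTCTTCTGTTGCTTTCACTGATGATTACACTCATGCTATTT
TCACTGGTTCTAAGCCACCAATGCCAATTCTTTTCATGGTTATGGATCATACTGCTGCTTCTGGTGAAAACCTTAACGGT
TGGTTCAACCTTATTGCTGCTGCTCTTCAAGTTTGGTGGGAAGTTTCTGCTTTCAGAGATTCTAAGGGTCAAAACCCAGC
TGATGCTATTGGTAGAAGATGGGGTATGGGTAGAATTTTCACTGAAATTTCTGTTACTGATACTGGTGTTCCAGTTTGGG
GTATTGTTGCTCATTCTTTCCTTAGATGGGGTCTTTCTGCTGAAACTGGTAACGCTCTTTCTGATAAGACTGCTGGTGAA
ACTGTTTAA
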