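>scaffold_CcPIP4;1
CATTCTAAGGGTTCTACTGGTCAAGATTACTCTAGAACTCAATCTGATAACCCAGGTTCTCTTGGTAACGCTACTCATTT
CAACCATCCACAAAAGACTCCATCTGTTTACCTTTTCGTTCTTTTCAGAATTATGTCTGCTAACTGGCTTGGTCAAAAGG
TTATTGGTTACGCTGATGCTAACTGTAACGGTACTTCTTCTCAAGGTAGAACTTTCGGTCTTCTTACTGCTCTTTTCGGT
TCTACTGCTGTTTTCCAACTTTGGCTTTTCGGTCCAGGTGAAAAGTACACTGATGAAGAAGGTGCTCATGAGTATCGCGA
TCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATTGCTTAACT
CCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCACACTGTCCG
GTGATAACCTGGCCGGATAGCCTAGAGGTGCTACTGGTGGTCATTCTATGGAAACTGCTAACAAGGTTTCTGCTTTCAGA
GTTAACCCAGCTGTTCTTACTGGTTTCTGGGCTGCTCTTACTACTACTAGATCTCAATGGATGTGGGCTTGGGCTTGTGT
TATTTGGAGATTCAGTCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACGAGTGGT
CTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACTCTGGCTTTAACCGTTG
TGTCGTATGCTGCGCGAAGTTCCAACTTCTGGTGGTGGTGCTAACGGTTCTTCTGTTGCTTTCACTGATGAAATTCATCA
TCTTATTTTCACTGATTCTTGGTCTATGATGTCTATTCTTGAAATGGTTATGGGTCAACAAGCTGCTCATACTGAAACTG
TTTCTCTTTGGTTCTTCCTTATGGGTGCTGCTCTTATGCATTGGTGGGTTGTTTCTCATTTCAGACCATCTAAGGGTGAA
AACCCAGCTGATGGTTGTTCTAAGAGATGGGGTGAAGGTAGAGGTTGGACTTGTGGTTCTGTTACTTTCGATACTGTTCC
AGCTTGGGCTCCAGTTGGTGGTGAATTCCTTTCTTGGGTGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTA
CCTCCACACCAACGGCACAGCTAGGACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAG
TCACCGTACCCTAGAGGTCGCGACCTTGTGGCTCACCCCAGATGCTTTCTGCTGAAACTGGTAACGCTCTTTCTGATAAG
ACTGCTGGTGAAACTGTTTAA
>scaffold_CcPIP4;2
TTAAACAGTTTCACCAGCAGTCTTATCAGAAAGAGCGTTACCAGTTTCAGCAGAAGTCATCTCCATCAAATGCAACTCCC
TTTATCACCGCGTTATAGTACTCTTGATAAGGTAGGACTATTTCGTCTCAGAACCCAAGAAAGGAATTCACCACCAACTG
GAGCCCAAACTGGAACAGTATCGAAAGTAACAGAACCACAAGTAGAACCTCTACCTTCACCCCATCTCTTAGAACAACCA
TCAGCTGGGTTTTCACCCTTAGATGGTCTGAAATGAGACCAAACCCACCAATGCATAAGAGCAGCACCCATAAGGAAGAA
CCAAAGAGAAACGTTTTCAGTATGAGCAGCTTGTTGACCCATAACCATTTCAAGAATCATCATCATAGACCAAGAATCAG
TGAAAATTTGAGAATGAATTTCATCAGTGAAAGCAACAGAAGAACCGTTAGAAGCACCAAGAGAAGTTGGAACTCAGCTT
TGAAATAAGAACTTCCTAAAGTTTCACAATCCTGTTGTTACTAATAAGTCGTAGTCTTACACTGAAAATCCAAATAACAC
AAGCCCAAGCCCACATCCATTGAGATCTAGTAGTAGTAAGAGCAGCCCAGAAACCAGTAAGAACAGCTGGGTTAACTCTG
AAAGCAGAAACCTTGTTAGCAGTTTCCATAGAATGACCACCAGTAGCACCTCTCGCCGAGTTGCGCTGACATTGGGCCTT
GCATATATGAGGACGAGACGGAACACTAGATTTTTCAGTGTCCACCAGCGCAGCAGAGGCACCCGGACAGCCGCAGCTCC
GCTCAGTCATGTAAAAATCGACGACATCGAGTAGATGCACCGTTGGGACTGATGCTTACCTTCTTCATCAGTGTACTTTT
CACCAAGACCGAAAAGCCAAAGTTGGAAAACAGCAGTAGAACCGAAAAGAGCAGTAAGAAGACCGAAAGTTCTACCTTGA
GAAGAAGTACCGTTACAGTTAGCATCAGCGTAACCAATCTTCTTAATACCAAGCCAGTTAGCAGACATAATTCTGAAAAG
AACGAAAAGGTAAACAGATGGAGTCTTTTGTGGATGGTTGAAATGAGTAGCGTTACCAAGAGAACCTGGGTTATCAGATT
GAGTTCTAGAGTAAGATTGACCAGTAGAACCCTTAGAATG
>scaffold_PpPIP1;1
CATTCTAAGGGTTCTACTGGTCAAGATTACTCTAGAACTCAAAAGGATAACCCAGGTTCTCTTGGTAACGCTACTCATTT
CGATCATCCAGAAAAGACTCCATCTGTTTACCTTTTCGTTCTTTTCAGAATTATGAGAGCTAACTGGCTTGGTATTCAAG
TTATTGGTTACGCTGATTGTAACGGTTCTCAAGGTAGAACTTTCGGTCTTCTTACTGCTCTTTTCGGTTCTACTGCTGTT
TTCCAACTTTGGCTTTTCGGTCTTGGTGAAAAGTACACTGATGAAGAAGGTGCTCATCAAGGTGCTACTGGTGGTCATTC
TATGGAAACTGCTAACAAGGTTTCTGCTTTCAGAGTTAACCCAGCTGTTCTTACTGGTTTCTGGATTATGCTTACTACTA
CTAGATCTCAATGGATGTGGGCTTGGGCTTGTGTTATTTGGAGATTCAGTATAAGTGTGACACCGTTATTCTCAGGGTCC
TCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATGAAGGCTTGTGAGGAGAGTTCCAACTTCTGGTGGTGGTGCTAAC
GGTTCTTCTGTTGCTTTCACTGATGAAATTCATCATGCTATTTTCACTGATTCTTGTTCTATGATGATGATTCTTGAAAT
GGTTATGGGTCAACAAGCTGCTCATACTGAAAACGTTTCTAACTGGTTCTTCCTTATGGGTGCTGCTCTTATGCATGTGT
CCTGGTGACATGTCTCATAACGCAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGCCGCGGGAACATAGGCTTG
TTTTATAATGACGGCTCGTGTAGGTTTATATCTGCCGCGTTAGGATCCTGTGCTAGGACGAGAGAGAGAACAGAGGTCGT
AGGTGCAACGCTACTTATTCTTTGGCCCAGTGGTGGGTTTACTCTCATTTCAGACCATCTAAGGGTGAAAACCCAGCTGA
TGGTACTTCTAAGAGATGGGGTGAAGGTAGAGGTTCTACTTGTGGTTCTGTTACTTTCGATACTGTTCCAGTTTGGGCTC
CAGTTGGTGGTTCTTTCCTTTCTTGGGTCCGAGTCCCTAAGAAAAGTGAACACCTAGTATTCATTAATTATTCAAAGCGT
TGGGAGGGTCTTTCTGCTGAAACTGGTAACGCTCTTTCTGATAAGACTGCTGGTGAAACTGTTTAA
>scaffold_PpPIP2;1
CATTCTAAGGGTTCTACTGGTCAAGATTACATTAGAACTGGTTCTGATAACCCAGGTTCTCTTGGTAACGCTACTCATTT
CGATCATCCAGAAAAGACTCCATCTGTTTACCTTTTCGTTCTTTTCAGAATTATGTCTGCTAACTGGCTTGGTATTAAGG
TTATTGGTTACGCTGATTGTAACGGTTCTCAAGGTAGAACTTTCGGTCTTCTTACTGCTCTTTTCGGTTCTACTGCTGAT
TTCCAACTTATGCTTTTCGGTCTTGGTGAAAAGTACACTGATCTTGAAGGTGCTCATCAAGGTGCTACTGGTGGTCATTC
TATGGAAACTGCTAACAAGGTTTCTGCTTTCAGAGTTAACCCAGCTGTTCTTACTGGTTTCTGGGCTGCTCTTACTACTA
CTAGATCTCAATGGATGTGGGCTTGGGCTTGTGTTATTTGGAGATTCAGTCCTATAATTCAGTGACGCCTTTCGACACAC
ATCTCATGGTGGGACTCGTGGTGTAAGTGGGTTCCCCCTATTTAACAGTTCCAACTTCTGGTGGTGGTGCTAACGGTTCT
TCTGTTGCTTTCACTGATGAAATTCATCATGCTATTTTCACTGATTCTTGGTCTATGATGATGATTCTTGAAATGGTTAT
GGGTCAACAAGCTGCTCATACTGAAAACGTTTCTCTTCTTTTCTTCCTTATGGGTGCTGCTCTTATGCATGTCTCGGGAG
GAAGAGTTGGCAAATTGTGTTCCCTATGCGGCTACTACGGAGCCACGTGTAGCACTGGGATGCTGGCGACCAATCCAGTG
GTGGTGGGTTTCTCATTTCAGACCATCTAAGGGTGAAAACCCAGCTGATGGTACTTCTAAGAGATGGGGTGAAGGTAGAG
GTTCTACTTGTGGTTCTGTTACTTTCGATACTGTTCCAGTTGAAGCTCCAGTTGGTGGTGAATTCCTTAAGTGGGTTCTA
TCCAGTGCATAACTCTTCATCTCAATGATAGTAGCGATATACTAAGGAAGAAAAGGTGCGCTATGTCGTAAAGGATCCAT
TTAAAAAGCCGAATTTATTCCCTAGAAAAAATAATGCGAAGTCGGTCGTAGATTCGCTTGTATTATGTTGTCGCGACCGA
ACCGACTAGATCCAGATGGACCAGGGTCTTTCTGCTGAAACTGGTAACGCTCTTTCTGATAAGACTGCTGGTGAAACTGT
TTAA
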