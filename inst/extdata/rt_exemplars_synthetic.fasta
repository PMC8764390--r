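>RTX01 clade=athila superfamily=Gypsy synthetic=true
ACCTGCCGAAATAAGGACAGCTTCGTGTCGCTAGTACGGGCTGAGTTGGTTCCTGGGACACGGCTGCGGCGGCACTTTCC
AATATTGACTACGTTGCTGACGGGCGCAATTAGACTGTACCTAGTTTAACGAATATGTTGATTGACGCCATATGTAAGCT
ACGTCATGAAACGCCGCCGTATGAGGAAGGGTGCTATTTTAACCAACCCCCGTATTAGGCTCGATGGTGAGACGACTCGG
ACGAGGCTGTTCTGAAATCTATCAATCCTGTTAACGTGTGACCGGTGGCAGTCCACATCGGAAGCGGTCGATGACTCCCC
ACTCCGCTTCTTCCTTTCCGTTAGATTAATACTCTATCCAGCCAAACATTAGACTCGTAGTATCCTGGATCACAGCGCTC
AAACCGTACGAGTTAAGTTCAGTTTCGTGCCTCCCGCGAGGTTACTTAATGGTAGGCTCGCCACCAACTTGTGACCCCAT
AAGCACCCGGCAGTAGACGCTTGCAGGATAGCCGTACCGTCTCAGGTCGGCCCCCGCCCTGTTCGTCTGTTACGCCACAT
CTGTTCCATTATTAACAAGCGAGGGATGGGCTAGAGATAG
>RTX02 clade=crm superfamily=Gypsy synthetic=true
AAACTTAAGCAGGGCACCCGCTTACCGTGTGGCTTAGCTAGGCCGGGTAACGGTCATCCGCCTCGATATCGTACTCGCCT
ATACGAGGCGGATCTCTTACAGAGTCGAAGGAAGATGCTGTAATCTTTGTACGTAGTGAAGGATGGATAGAGGAGGGCAC
TCGCTCACTGTTGAGAGGCTTCATTGCCTTTCCTATAGTTAGTCCGGAGTGCAATTCCGCTCGGCAAAATCTTTCGATTA
ACGCGCTCGGTATGGGACTAATCCAATAATCGCAAGCTCTCCCATGGCGGAATTAACACATCGCATTGCAGTCTCGGGCG
AGCGGCGCCATCAGACTACTTCCCCCGGTAGACAATACCTGCTCTAAATTGCGAACTCAACAAACGTAGGATGAAGGTAG
GACGCTTACGTGGGTTATATGATCGCCCATGACATCCTTCACCAAAAAACCTTGTCTGAATCCAGCGTAATTCGCCCGGT
AGACGTCAGGTATACCCTTAATCGTGTCCGAGCAAGGTCGTACATTACGATGCAGGGGTTAAAATGTAAGACAGGAGCAC
TCGACTGAACTCCCAGTCAGTCCTCGCAGTACAACCCTAA
>RTX03 clade=del superfamily=Gypsy synthetic=true
CTGGAATCGCCAACAACCGTATGGGCGTGTGGATTATGTCTGAGGACGGAGGCCCTGGTCACGCAATACCCTGTTATCCC
AAGGAGATGGCAATCCTTACGGGTGAGTCCTAAACTCGGGTGTACTGGGCGTGTACCAGGCTGGCGCTTTCTCCGGGCAA
ACTTTCATCACCGCTCTGTAATAAATAAACCGATGGGACGGGCATATCTCCTAGGTGCGGGCAATGAACTGCCTAAAGGA
CTCCCTTCAAGCACTGAGGCCTCACGTAAGTCTCTGTTCCCTCGCCAGTGTGTTACCGAAAACTTGCGACTGGGTGTAAA
TTGCACTAACTTTCCATGCACTCCCGTGGGCGTATTAGGTGGTTTCATCTGTGGGGGTTCCGACGAAACCGTTCTTGCGA
CAAATGGGAGGGAGTGCTGGAATGCCATATCACAGCGGGATGAAAGCACAAATGTGCTGGAAATGCCACAGTATGGGACG
CACACGAACAATCATCCATGTCTACGATACACCAACTGGTCAACCCTATCGATGGAAACGACGATCCAGTCAGTATACGT
CCATGTAGGTCATGCCAAACACTGCGAAAGCATCTCCGTG
>RTX04 clade=oryco1 superfamily=Copia synthetic=true
GAGGGGCTGGATTGCTTGTAGTATTTTCTACTTAGTTAAACTCAAACGTACTTGCTGGAGTGCAAATTGAACTCCTATAT
ACGCCGGCTTCAACTTATCGTGTGGTATCTTTCGCGGGGAGCATAGGCTGCCATCGCTCCAACCATGGATTTACGAATAC
AAGACGGGGGTACGAGGAGGACGTCTGCAACAATGAAGTGCCCCGTTATTCCCCACGACTCTGTCACCGATTAGGCAAAC
AGTACAAACTTAAATGCTAGCATTGTCGCGTCATGCCAGGGGCTAGTGAAAGTGAGAAGAATCCCATGGCCAACAACACC
AACGCCTCGCACGTTACGCTATGAGTGGTTATTGGCGCCAGGGCAATATGACGTCGCGTGGGGTTTCCCGATAGTAAAGA
GGGCTCCAACTATTATCTACAATTACGAGTCGTCCTTTACAGACGATGACATCAAAGCAACTTACGCGGATCCTGTGGCA
GATACTTCGTTAAAAGCCATCCCCCACAACATAGGTTCACCTTAGCCAACACGCGTGCAGTACCATGGGAATTATAAACA
CATTAAGTGGGGCAACCGAGTGATAAATAAATGGAGATGC
>RTX05 clade=oryco2 superfamily=Copia synthetic=true
TCGAAGAAGCCGCAAGACGACAGGTCTTTCTCCGCTCATTTACATGGTGCGATTTCAGCCGCTTCTTATCCCAGCTAATT
CATATTGGGTAAGATGTGGGCCTGCTATTCTAAGCTTCATACGTAGCGAAGTCTAATCAGTTACTACCTTAGTAGCCAAT
ACCCACCGCTCAACTACGGTGAAGTCTCAACTTCAGGGGGAATGACGTTCTCATGAAAGACCACTACCTTCTCCAGTTCG
CTGTAGCCAACGAACGCAAACTCAGATCAATATACCACGGGTTGGTGCAATGCTTAAACTGCGCTGGTGCCGTCGGGAAG
AGTATCGCACCTGCTGCCACGTGACATGATAACTTGTGTTTATGTTTGACTAACTGGAGCACCCTGAGGCGCTGAAGCGC
GGGGCGGCTCCACGCTATTGGGCGTTTGGCGCGGACAGGGACGCGGGCTAAAGAGAACGGCCTAGTATTCAAGAAGTGTC
TACCAGAGCGTAGGAACATTATTCAAGCCACGCGTATAAGAGGGACGCAAGTAATGAGGATGTCGTGTAAGGTGCTATCG
GGTCCAAGGATGTGTACTGAAGGCACTTTGTACAATTACA
>RTX06 clade=tork superfamily=Copia synthetic=true
AGTACTATATGACGGTTTTATTTTTACCCCATACGTCTGTCGAATTTCGTTTATCCCAGGGGGTGGGATTGCTCCTCAAA
TCTCTTCCCCCTTATTCTCTCTAGCGACAACAAATATCCAGCGAAGGTGGAGTTCGCACGCCGTCGAGCCTAAAGGCTGT
CCGGACGCGCGTAGGCGGTTCGCACAAGAGGACCGCGCTAGACAGGAGGTTGTTACGCGATCTCTTGCATCACGGAAAGC
CATACACCGCCTCGTTGGCAGCTATCATCTCTAAACAACACTGTTGGCCATGCAGCTTTAGTGTGCTAGCGCCATACTAC
TGATTGGGGGCCTCTGCACAGGCAGGTGTGTATAACTGGTACGCGTCGGGCAGCCCCTCGGGAATTGGTACGGATAATGA
TCATGACAAGGTTCGAGAGAATGGGACGATGCTGTTACGACACATGTCAGTAAGGGTAACCTAGCATGTAGGGATTCGAG
AGGACTTATTCATTAATCAGGCTCGTCTCCACGTGTATTCTTAGTGCCACAGTGCCGCTGCTGAGGGAAAGTGCACCAGA
AGATTTACTTGTATGTAACGGGGAGAGCAAGTGAAATGGC
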