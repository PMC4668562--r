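>Ale|Copia
CGAAGAGCATTAAGTGAGGCTTTGGGCTTTATCAGTGTCCCAAACCCGACGCATCTCTCGACAGCATTTCTTCATGGCGAACTCGACGAGGAAATTTACATGGATCAGCCTGAGGGATTCGTAGTTAAGGGGCAGGAACATAAAGTATGCAGGCTCAAGAAGTCGCTATATGGGCTAAAACAGGCCCCACGTGCTTGGCCCGTTCTGCAAGTTGGTGATCTGCTAGATTGTGAGCGATACAAGTTCATATTAACAATC
>Ivana|Copia
AATCGAAAAAGGACCCTGCCTCTAAGAGCCACCCATAGTCGGCGGGCTTCTGTTCTTTCGACAGCGTTTCTCCACGGCGAACTCGACGAGGAGATATACATGGACCAACCAGAAGGTTTCGTCGTGAAGGGACAAGAGCACAAAGTCTGCCGTCTTAAAAAGAGTCTTTACGGGCTAAAACAAGCCCCCCGCGCTTGGACTGAAAAATGGCAAACCTCGGCTCATATGAGAGTAACGCGACCCCAAAGTCCCACGGGC
>Bianca|Copia
GCCAACACCTGCCCCGTCAAAACGTTCATGTACTCTGACGAGCCACTCCCGATGACGAATACGGCCTTTCTACATGGTGAACTGGATGAGGAAATTTACATGGATCAGCCAGAGGGTTTTGTCGTTAAGGGACAAGAACATAAAGTGTGTCGACTCAAGAAGAGCCTATATGGACTAAAACAGGCTCCACGCGCATGGTGGCTTAGGTGTATGAACAAAGTGCGACGCGCTGGGGCGAATTGCCACATGCGTAGGATT
>Angela|Copia
CGACTTAATCCGAGAGACCCCCCTTATCCTCATAGGGTCGGGGGTATCTCTACCGGCGCGACAGCCTTCCTGCACGGTGAGCTGGACGAGGAGATCTACATGGATCAACCGGAAGGCTTTGTTGTTAAGGGCCAAGAACACAAGGTGTGCCGACTCAAGAAATCTTTATATGGCTTAAAACAAGCTCCTAGGGCCTGGTGGCGTAACTTTCTCACGAGTCGTGGCAAGGGTTTACGCCATATTGCAAGCATCTGTCTC
>TAR|Copia
CTACGCGACGGGGACATGCAACTTGCGGTCGAACCCGGGGCCTCGGCCACACCGGACGGGACGGCATTTTTGCATGGCGAGCTTGATGAGGAAATCTACATGGATCAGCCAGAAGGTTTTGTCGTTAAAGGACAGGAGCATAAGGTATGTCGTTTAAAAAAGAGTTTATATGGGTTGAAGCAAGCTCCGAGAGCCTGGCGATCTGCGACGACAAGGCCGGTATGGTCTTACTCTGTACCCTTTAGAAACGCGAGCGGC
>Maximus|Copia
CTACTTTCTCTTGGCGACCCGGATGAAAGGACTCGTGACCGGGAAGATGGAAGTCTCGTAACAGCGTTCCTCCATGGCGAACTAGACGAAGAAATTTACATGGATCAACCAGAAGGCTTTGTAGTGAAAGGTCAGGAACATAAAGTCTGTCGATTGAAAAAATCACTGTATGGCTTGAAGCAGGCACCCAGGGCGTGGTATCGGACAGGATCAGCACTCGATACCAGGCAAATTAGCTTGTCTATTGGTGACTTAACT
>Tekay|Gypsy
ACTGATTCTGGACACGATGGCACCCAGACCCTAAAGCATACGTCTTATCCAATTTTCTGCCCTTTCGGGTTGAAGAACGCGCCCGCTGTATTCCAACGCAAGATGGATAACTGTTTCAGAGGCACAGAAGGGTTTATAGCAGTGTATATCGATGATATCCTGGTTTTTTCGGAAACTCTGGAAGAGCACGTGCAGCATCTAGAGTCGTTTGGGAGTTTCAGTTGTGGTAATGGCTGCTATACCGGTGCTTTGACTCAGCGATTT
>Galadriel|Gypsy
CAAGGCTTTTTGGACTTCTATCGAATGAAAAAATCGATTGCTAGGGTACAGCTGTATAGACCTTTTGGGTTAAAGAACGCACCTGCAGTTTTCCAACGGAAAATGGATAACTGTTTCCGAGGAACGGAAGGTTTTATTGCGGTTTATATCGATGACATACTCGTCTTCAGCGAAACCCTTGAGGAGCACGTGCAGCATCTTGAAGGACCCTGGCGGTGCTGTGCGACGTACGAGGGAAAGGTTAGATATACGGGTAGTTTTGAA
>CRM|Gypsy
GACAAACGACGAGATAAGAAGGCGCCGGACGGCGAGTCGGAAGCTACTGGTACGCCCATACCCTTTGGCCTTAAAAATGCGCCAGCCGTTTTTCAGAGGAAAATGGACAACTGCTTTCGTGGTACCGAAGGTTTCATTGCTGTTTATATTGACGATATTTTGGTTTTTTCGGAAACATTGGAAGAACACGTACAGCATTTGGAGCATGTAAATGCCGTGGTATTCCGAAACGTACGTAAGTCTTGTCCCAGGGTACAGCATTCC
>Reina|Gypsy
AATCGAAAAAGGACCCTGCCTCTAAGAGCCACCCATAGTCGGCGGGCTTCTGTTCTTTCGCCATTCGGTCTCAAGAACGCTCCAGCGGTGTTCCAGCGCAAAATGGACAACTGTTTTCGAGGTACGGAGGGGTTCATAGCAGTCTACATTGACGACATTCTTGTATTCAGTGAAACGCTCGAAGAACATGTCCAGCACCTAGAGACTGAAAAATGGCAAACCTCGGCTCATATGAGAGTAACGCGACCCCAAAGTCCCACGGGC
>Athila|Gypsy
AACCCTTCGGTGCTGTATAGATTGTTTAGGGTAGGAGAGGAACACGAAGATCCATCAGCACCCTTTGGCCTAAAGAATGCTCCCGCAGTATTCCAGCGCAAGATGGACAACTGTTTCAGAGGAACCGAGGGATTTATTGCGGTTTACATAGATGATATACTTGTGTTCAGCGAAACGTTAGAAGAGCACGTCCAGCATCTTGAACAAGACCCTTTTGAGATGGCCCTCTTACCCCTGCAACACTTGTTCATAACCTTCCAGGCG
>Ogre|Gypsy
ATGAAGATCAATTTAACGCCTCGGTCCCTTGCCAGGTCATCAGTGTTCAACTGGGCCATACCCTTCGGCCTGAAAAATGCGCCCGCCGTCTTTCAGCGCAAAATGGATAACTGCTTCCGGGGTACTGAAGGCTTTATCGCTGTCTATATAGACGACATCCTTGTCTTTTCCGAAACATTAGAGGAACATGTACAACATTTGGAACGCGCGGTGGTTGCTAGACTTCCTCTAATGTGGGTACACCAAAAGTGCGTGTGGCGCAGT
>Tat|Gypsy
CCAGGTAGGTTGGGTAACCAGATCAGCAAAGCGTTCACATATGGACTTTCTCCAAGACGACCGTTTGGATTGAAGAACGCACCTGCAGTCTTCCAGAGGAAGATGGACAATTGTTTTAGGGGGACCGAGGGGTTCATTGCGGTCTACATTGACGATATCTTGGTCTTTAGTGAAACATTAGAGGAACACGTGCAACATCTGGAAAAAATGGTACACGTTTGGCGCAGAGACAGTGCTGAGTTGTATAGCGTTGTGACAACCAAG
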