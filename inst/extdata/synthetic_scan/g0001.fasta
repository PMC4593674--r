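>dolphin
GTGGCATCTCCACTCCAGCCCTGGAGGCTGCCGACCGGAATACAACGCAGCACGGAACCAGACAGGGAACATCGCCATGCGGCTAGTCATATAGGACACCAGGCTAGGACTAGTTCGTGGTTCCGGGGCCGCTCTCCCAAAAGAATCAAGACCCACACAAGAAGAGTTCGAACCATTCGGATGATAGTACCACGTAAATCGGAAAGGCAAGAAAGAAGGTCGCAGAGCGGGACTCTAGGCGGCCAAGTCACTGGTTTACGACACGATAAAATAAGAGCTAGCGAAGCCATCTTATTCGGGGACGTGTCACCTGACGCCGCATCGAGGGCATTGCCCTCCCGTAACAGGGTTTTGGACACGTCAAGAGAACCGGGTAAACAGCCAAGGGAAGGGGACTTGGAGGTCTGTGATCTAAAGTCTAGAAACCTACGTCGATTTAGGGCACATGGTAGGCAACCATTCTGCGAAATTAGGGGTGATGGACATGTGGCACTGGCACTAGATACTCGGTTGTGTAACTCACGCAATATACACCGCAGTACGGTGTTGTATATCTGCCCAACAAGCCAACCACCTAGGATCGGGACCTGTGTAACTATTCGGAAATGGTATAGAGTTTTGTTATCTTCGGTCAGAATTGTCGCGAAACCTTGTAAGGCGAGGACGGCACCGTATATCCAGATACCCTCCTGTGAGATCAAGGATCTGTTTACTACAGTTTGTGTAGAATACCCTATTTATATACACACGTCCCTATGGGCTGCCAGTCTTTGTAATGTACTAAGCGACAGCAGAAATAGGCTAGTATTAAACTCATTAATGGTTTTACAGCTCGGCTGTCTAGGTAAAATATCGTCTCCGCATACTCACCTATACGCGCTTCTGCACTGTCTTGTCGAATGTTTAGACGTTGTCCGCGGTATCGTCTATGACATCTCCGCGTTGAAGGCTCGTAACGAACGGATTTCGACAAATGCTCGTAGG
>whale
GTGGCATCTCCACTCCAGCCCTGGAGGCTGCCGACCAGAATACAACGCAGCATGGAACCAGACAGGCAACATCGCCATGCGGCTAGTCATATAGGACACCAAGCTAGGGATAGTTCGTGGTTCCGTGGCCGCTCTCCCAAAAGAATCAAGACCCACACAAGAAGGGTTCGAACCATTCGGACGATAGTACCACGAGAATCAGAAAGGCAAGAAAGGAGGTCGCAGAGCGGGACTCTAGGCGGCCAAGTCACTGGTTTACGACATGATAAAATAAGAGCTAGCGAATCCATCTTATTCGGGGACGTGTCACCTGACGCCGCATCGAAGGCATTGCCCTCCCGTAACAGGGTTTTCTACACGTCAAGAGAACCGGGTAAACAGCCAAGGGAAGGGGACTTGGAGGTCTGTGATTTAAAGTCCAGAAACCTACGTAGATTTAGGGCACATGGTAGGCAACCTTTCTGCGAAATTAGGGGTGATGGACATGTGGCACTGGCTCTAGATACTCGGTTGTGTAACTCACGCAATATTCGCCGCAGTACGGTGTTGTATATCTGCCCAACAAGCCAACCACGTAGGATCGGGACCTGTGTAACTATTCGGAAATGGCATAAAGTTCTGTTATCTTCGGTCAGAAGTGTCGCGAGACCTTGTAAGGCGAGGACGGCACCGTATATCCAGATACCATCCTGTGAGATCAAGGATCTGTTTACTACAGTTTGTGTAGAATACCCGATTTATATACACACGTCCCTATGGGCTGCCAGTCTTTGTAATGTACTAAGCGACAGCAGAAACAGGCTAGTATCGAACTCATTAATGGTTTTACAGCTCGGCTGCCTAGGTAAAAGATCGTCTCCGCATACTCACCTATACGCGCTTCTGCAATGCCTTGTCGAATGTTTAGACCTTGTCCGCGGTATCGTCTATGACATCTCCGCACTGAAGGCTCGTAACGAACGGATTTCGACAAATGCTCGTAGG
>hippo
GTGGCCTCTCCACTCGAACCCTGGGGGCTGGCGAGCAGAACACGACGCAGCATCACACCGGACAGGCAACATCGCATTGCGGCAGGTCATATAGGACACCAAGCTAGGCGTAGCCCGGGATTCCGCGGCTGCTCACCCAAAAGAATCAAGTCCCACACAAGGAGGGTGCGAACGATTAACACGATAGGTCCACGGAAGTCGGAAAGGCAGGAAAGAAGGGTGCAGAGCGGGGCGCTTGGCTTGCAAGTCCCTGGTTTCCGCCATGATAAAATAAGAGCAAGGGAAGCGATCTTATTCGGAGACGTATCACCTGACGCCCGCTATCATGCATTGCCCTCCCCTAACAGGGTTGTGGACATGGCAACAGAACCGGCTAAACAGACAAGGGAACGAGACTTGGAGCTCAGTGATTTAAAGTCCAGACACCTACGTAGATTTAGAGCCCCGGGTGTGGAACCATTCTGCGACATTAGAGATGATTCCCATGCGGCGGTGGCACTCGACACTCGGTTGTGTAACTCACGTGACGTACACCGTATTACGGTGTTATCTCTCAGCCCAACAAGCCAACCACCGAGGATCGTGACCTGTGTGACTATTCGGAAATGGCATAAATCTGTGTTATCGTCGGTGAGAGTAGTCGCCAAACCTTGTAAGGGCCGGACGGCCCCGTATATCCAGATACCATCCTATGAGATCAAGGGTCTGTTTACGACAGTGTGTGGAGAATACCCGAGATATATACACATTTCCCTAAGAGCCGCAAGTCTCTGTGATATACTAAGCGATAGCAGAAACAGGCTAATATCAAACCCATTAATGGTTCTACAACTCGGCTGTCAGGGTGAAAGATCATCTCCGTATGTGCACCTGGAGGCGCTTCTGCGGTGTCTTGTCGAATGTTGGGACCTTGTCCGCGGTATTGTCTATGGCATCTCGGCGCCGACGGCTCGAAACGAACGGATTTCCGCAAATGCTCGTAAG
>pig
GGGGCCTCTCCACTCGAACCTTGGGGGCCGCAGTGCAGAACACGACTCAGTATGACGCCGGATAGGCAACATGTCACTGCAGCAGGTCATATGGGACACCAAGCCATGGATAGTCCGTGCAGCAGGGGCCGCTCTCCCAAAAAGATAAAACCTCACACGTGGAGGGGTCGGACCATTCGGTTGACAAATTCACGTAAGTGCGAAAGACAAGTGAGAAGATCGCATAGCGGGACCCTACGCTTGCAGGTCCGTTGTTCAAGACATGATAAAATAAGTGCTAGCGAATCCATTTTATTCGGAGACGTGTCACTAGACTCCGCCTCACACGCCTTGCTCTCCCGCAACAGGGCGTCAGACGCGGCAGGGGAACCAGTTAAACAGCTAACTGAACGGGGCCTGGATGTCAGCCGCTTAAAGTCAAGACACCTACGCAGATTTAGGGCACCTGCTCTGCTACCATTCTGCGCAATAAGGAGTGGTGGACATTCGGCGCTGGCTCTTGACACCCAGTTATGTAACTCTCGTAAAATGCTCCGCAGTCCTGTGTTATCAATCTGCCCAATAAGCCAACCACCTGGGTTCGGGACCTGCGTAACTGTCCGGAAATGGCATAAAGCTGTGGTATCTTCGGTGCGAATAGGAGCTAAACCTTGCAAGACACCGCCGGAGCCGTATATACAGAGCCCCTCCTGTGAGATCAAGGTACTATTTACGACAGTCTGTGTTGAGTACCCAAGATATATGCACATCTCCCTCAGGGCTGTCAGTCTCTGTAAAGTACTGAGCGACAGCAAAAACAGGCTCGTACTTAACTCGTTAATGGTTTTACAGCTCGGATATCCGGGGGAGGGATCGTCTCCTCATGTGCACCTGGAGCCGCTCCGACGGTCTCTTGTCGAATGTGTGGACCTTGTGCGCGGCATAGTCTATGGCCGCTCCGCGCCGACGGCTCGAAACGAACGGATTTCCGAAAACGCGGGTCAG
>camel
ATGGCGTCGCCACTCAGACCCTGGGGGCCGCAGAGAAGAACACGAGTCAGCATGACGCCGGATAGGCAACACGGCACTGCGGCTGGTCATATGGGCCACCAAGCCAGGGCCAGTCCGTGCAGCCGGGGCCGCTCTCCGAAAAGAATCAAGATCCACACAAGGAGGGAGTGGACCATTCGTATGCCAGCTTCACGTAAATCAGAAAGACAACAAAGAAGATCTCAGAGCGGCACACTACGATTGCAGGTGCCTTGTGCGCGCCATGATAAAATAAGGGCTAACGAAGTCATCTTATTCGGAGACGTGTCACCAGACATCGCCTCGCACGCGTTGCCGTCCCGTAACAGGGTAGCAGACACGGCAGGAGAACCAGTTAAACAGCGAAGGAAACGGGACTTGGAAGTCAGCGATTTGAAGTTAAGACACCTACGGAGATTTAGGGCGCCCGGTCTACTCCCCTTCTGCGAGACCAGAAGTGATGGACATTCGGCTCGGGCTCTCGACACCCTGTTATCTAACTCACGTAAAATCCACCGCAGTTCTGTGTTATCTCTCTGCCCAATAAGCCAACCACCTGGGTTCGGGACCTGTGTCACTGTACGCAAATGGCAGAAGGCTGTGTTATCTTCGGTGAGACTTGGAGCCAAACCTTGCAAGACGAGGTCGGAACCGTATATCCACAGCCCCTCCTGTGAGATCAAGGCACTATTTACAACAGTCTGTGTAGAATACCCGAGATATATGCACGTCTCCCTAAGGGCTGCCAGTTTATGTAAAGTATTGAGCGAAAGCACAAACAGGCTCGTATCCAACCCGTTAGTGGTTTTACAGCTCGGCTATTCGGGCGAAGCATCGTCGCCTCAAGTCCACCTAGAGGCGCTTCAACCGTGTCTTGTTGAATGTCTGGACCTTGTCCGCGGCATCGTCCTGGGCCTCTCCGCGCCGATGGCTCGAAACGAACGAATTTCCGCAAACGCGCGTAAA
>cow
GTGGCTTCTCCACTCAAACACCGGGGGCCGGCGAGAAGAACACGACTCAGCATGACACCAGATAGGCATCATCGGACTGCGGCTGGTCATATGGGACACCAAGCTAGGGATAGCCCATGCAGCCGGGGCCGTTCTCCTAAAAGAATCAAGACCCACACAAAGAGAGTTCGAACCATTCGTTCGATAGGTTCACGTAAACCAGAAAAGCAGGAAAGAAGGACACAGAGCGGGACCTTACGCCTGCAAGTCCCTGGTTTACGCCATGATAAAATAAGAGCTAGCGAAACCATCTTATTCGGAGACGTCTCGCCAGGCTCCGGATCGCACGCGTTGCTATCCCGGAACAGGGTTTCAGACGCCGCTGGAGAACCAGTTAAACAGAGAAGGAAAGGGGACTTGGAGATTAGTGAGTTAAAATCAGGACACCTACGGAGGTTTCGAGCGCCTGGTTTGCAACCATTCTGCGAATTCAGAGGTGATCGACATTCGGCACTGGCCCTTGACACTAGGCTATGTAACACACGTGAAATACACCGCAGTTTGGTGCTATCCATCTGCCCGATAAGCCAACCACCCAGGTTCGGGACATGTGTAACAGTCCGGAAATGGAATAAAGCCATGTTATCTTCGGTAAGAATAGTAGCTAAACCTTGTAAAGCGGGAACGGCACCTTACATCCATATCCCCTCCCGTGAAATCAAGGCACTATTTACGAAAGTCTGTGTAGAATACCCGAGGTATATGCACATCTCGCTAAGGGGTGCCAGTGTCTGTAATGTACTAAGCGACAGCAGAAACAGGCTCGTCTCTAACACCTTAATGTTTCTGCAGCTCGGCTGCCGGGGAGAGGGATCGTCACCGCATGTCCACCTAGAGGCGCTTCATCGGTGTCTCGTTGAGTGTTTGGACCTTGTTCGCGGTATCGTTTATGTTACCTCCGCGCCGAAGGCTCGAAACGGGCGGATTTTCGCGAACGCTCGTACC
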