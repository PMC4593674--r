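>dolphin
CACCTACGTCGATCGAGGGGGGGACACCACCTCACTTGGGCGCTCAGGGATCCGAATCCCAATATATTCGTAATTGACGACCGCGTAGGAAGAAATGTTTCCGGCCGACGTGCGAGCCTCGAATGGCTCACTCATGCCAGCATGTTATCAATTCTGATGATGCTTGCCTTAGTCGGATGCATCTGCATGCTCCTACTACCACGGGAGTGTGAACCCTATGTCTCGCATTACACTAAGCATACTCGCCGCCACTATGCACAGCATAACGGTGACATGAGGAGGACAAATGCTGTAAATACTTTGATAGTATGCCAGCTCGGGTCGGCAGGCTCAACTAGCTATTCTCCTACACGAACGTCAGTCGTGAATGACTTAGCAACGTCGCTTCGGCGATGCCAGGTTATCAACCACGATTTTCTGCTGGAAGGTGCAGCAGAAGGTTCTTGCCTACCCAAACCCCCGGGCCATTTACTGGCGAACCTACGCAGTAGGGAGGATAAAGGTATAGTTGCAAGCGATGTGTACCAGATAGCTCCACCTGCAAGTGACTCAACACCTCCGATATCAGTCTCTAGCGCTCACGGCACCTATTTCCGTAAACGGGATTCTTCTAAAGCATGCTGCCTAATACAAGGGTCAATGGGCACGCTCCAGGGGAAGCCGGTTATTGGCTCGACTTTAGGGGCGTCGCCGGATCACGGCGCATCAGATATCCGCTGGGTAACAATAAAGAGGGAGCGAGCCGGAGCTTTGCTCACCGCTACCACTACATCTCCCGCTGGTCGGATTTCTCAGGCGACTTTAAGGAACGTCAAGTCCAAGTATCGAGGTGGTACGAATGCACTACTTCTCAAAGTGGGCGTCATGTCCATTTGGTTTTTGGTG
>whale
CCCCTACGTCGATCGAGGGGGGGACACCACCTCACCTGGGCGCTCAGGGATACGAATCCCAATGTATTCGTAATGGACGACCGCGTAGGAATAAATGTTTCCGGCCGACGTGCGAGCCGTGAATGGCTCACCCATGCCAGAATGTTATCAATTCTGATGATGCTAGCCTTAGTCGGCTGCATCTGCATGCTCCTACTACCACGGGAGTGTGAACCCTATGTCTCGCATTACACTAAGCATACTCGCCGCGACTATGCCCAGCATAACGGTGACATGAGGAGGACAAATGCTGTAAATACTTTGATAGTATGCCAGCTCGGGTCGGCAGGCTCAACTAGTTATTCTCCTACACGAACGTTAGTCGTGAATGACTTAGCAACGTCGCTGCGGCGATGCCAGGTTATCAACCACGATTTTCTGCTGGACGGTGCAGCAGAAGGTTCTTGCCTACCTAAACTCCCGGGCCATTTACTGGCGACCCTACGCAGTAGGGAGGATAAAGATATAGTTGCAAGCGATGTGTTCCAGATAGCTCCACCTGCAAGTGACTCCACACCTCCGGTATCAGTCTATAGCGCTCACGGCGCCTATTTCCGTAAACGGGATTCTTCTAAAGCATGCTGCCTAATACAAGGGTCAATGGGCACGCTCCAGGGGAAGCCGGTTATTGGCTCGACTTTAGGGGCGTCACCGGATCACGGCGCATCAGATATCCGCTGGCTAACATTAAAGAGGGAGCGAGCTGGAGCGTTGATCACCGCGGCTACTACATCTCCTACTGGTCGGATTTCTCAGGCGACTTTAAGGAACGTCAAGTCGAAGTATCGAGGTGGTACAAATACACTACTTCTCAAAGTAGGCGTCATGTCCATTTGGTTTTTGGTA
>hippo
CCCCCGAGTCGTTTTGGGGGGGAGCACCACCTCACTCGGGCGCTCGGCGATCCGGATTCGAACATTTTCGAAATGGACGACCGTGTAGGGAGAAATGTTACCGTCCGACGTGCGAGCCTTGAAGCACTCACTCGTGCTAGAATGTTATCAATCCTAACGGTGCTTCCCTTAGTCAGCTGCACTTGCATGCTCCTACTACCACGGGAGTGGGAACTTTATGCATCGCATTACACTAAGAATACCCGCCGGCACTATGCTCAGAATAATGGTTATATGAGGGGGACAAGTGCAGTCAACACTTTAATAGTTTGTAAGCTCGGTTCGACAAGGTCCACTACTTATTCTCCAACACGATCGTTAGTCGTCAATGGGTTAGCATTTGCGTGTCGGCGATGCCAGGTTATCAACCACGATTTTCTACCGGACGGTGCAGCGGAAGGTTCTTGCCTACATAAACTCCCGGGCCATTTAATGGCGACTCTCCGCAGTAGGGTGGATAAAGGTATAGTTGCAAGCGATGTGCACCAAATAGCTCCACCGGCGATTGACCTTACACCTCCGTTATCAGTCTATAGCACACACGATACATATTTTCGTATAAGGGATTCTTCTAACGCATGCAGCCTAATTCTAGGGTCCATGGGCGCGCTCCAGGGGAAGCCGGTTACCGGTTCGCCTTTAGTGGCGTCATCGGACCACGGCACGTCAGATTTTCGCTGGGTAACAATAAAGAGGGAGCGACCCGGAGTCTCGCTCAACCCTACTACCACACTCCCTACTGGTCGGGCTTCTCAGGTGACTTTGAGGAATGTGAAGCCGAAGTATCGACGTGGTACGAATGCGTTACTTCTCAAGGTAGGCGTCATGTCCATTTGGTTCTTCGTA
>pig
CCCCCACGCCGATCGGGGGGGGGGCTCAATATTACATGGGCGCTCTGGGATCCGGATTACAATATTCTAGAGATGGAAGACAGTGTAGACAGAACTGTTGTCGTCAGACGTGCGAGCTTCGAAGTGATCATTCATGCCATACTGCTCTCAATCCTGATGATCCTGGCCTCGTTTAGATGCACTTGCATGTTCCCTCTATCACGGGAGTATACAGTCTATGCCTCGCATTTCACAAAACATATACGCCACTACCACGCCCAGCATAATGGCTATATGAGGAGGACAGATGCTGTCAATACTTTGATAGTTTGCGAGCACGGTTCGACAGGCTCCACTAGTTATTCTCCGAAACGAGCGTTCGTGGTCAATGAGTTAGCATTGGCGTTTCGACGGTGTCAGGTTATCAACCACGGTCTTCTACTGGACGGTGGAGCGGAAGGTTCTTGCCTGCCTAAACTCCCGGGCCATTTACTGGCGACCCTGCGCAGTAGGGTGGATAAAGGTATTTTTGTCTGTCGTGTATACCAGATAGCTCCACCTGCGTGTATCCCTACTCCTCCGTTTTCAGTCTATGCCACACACGACACCTATTTTCGTAGACGGGATTCCACTAAAGCATGTAATTTAACTCAAGGGTCAATGGGCAGGGTTCAGGGGAAACCGATTACCGGCTCGCCTTTATTGGCATCAACGGATCAGTGCACGTCAGATATTTGCTGGGTAACAACAAAAAGGGAACGAGCCGGAGCCTCGCTCGACTCTACTACCACGCTTCCTTCTGGTCGGGCTCCTCAGGCGACTCTAAGAAATGTCAAGTCAAAGTATCGCCGTGGCACAAATGAGTTGCTGGTCAAGGTAGGGGTCATGTCCATCTGGTTTCTGATA
>camel
CCCCTACGGCGATCGGGGGGGGGGCTCCATATTACATGGGCGCTCTGGGATCCGGATTGCAATATTTTTGAGATGGAAGACCGTGTAGAGAGAACTGTTGTCGTCAGACGCGCGAGTCCTGAAGCACTCATTGATGCCAGAATGCTCCCAATCCTGATGATGCTTGCCGCATTTAACTGCACTTGCATGCTCCCTCTATCACGGGAATGTGAACTCTATGCACCGCATTACACTAAACATATACGCCTCCTCCATGCCCAGCATAATGGTTATATGGGAAGGACAGAGGCTGTGGATACTTTGATAGTTTGTGAGCTGGGTTCGATTGGCTCCACTCGTTATTCTCCCACACGAGCGTTAGTAGTTAATGAGTTAGCATTGGCGTTTCGACGATGCCAGGTCATCAACCACGATCTTCTGCTGGACTGTGCAGAGGAAGGTTCTTGCCTGCCTAAACTCCCGGGCCATTTACTGGCGACCCTAAGCAGTAGGGTGGACAAGGGTATTGTTGTAAGCCGTGTATACCAGATAGCTCTACCTGCGAGTGACCGTACACCCCCGTTTTCAGTCTATGTCACAAACGGCACTTATTTTCGTAGACGGGATTCCTCTAAAGCATGTAATTTAATACAAGGCTCTATGGGCAGGCCCCAGGGGAAGCCGGTTACCGGCTTGCCTTTATCTGCATCAACGGATCACGGCAAGTCAGCTCTTCGCTGGGTAACAACAAAAAGGCAGCGAGCAGGAGCCTCGCTCAACTCTACTACCACGTCTCCTTCTGGTCAGACTTCTCAGGCAACTTTGATAAATGTCAAGTCGAAGTATCGAGGTGGCATGAATGGGTTGCTCCTTAAGGTAGGGTTCATGTCCATCTGGTTCTTAATA
>cow
CCGCCGCGCCGAACGGGGAGGGGAAACCATATGTCATGGGCGCTCTGGGAACCAGATTCCAATATTTTCGCCGTGGAAGACCGTATAGAGAGAAAGGTCGCCGTCCGACGTGCGAGCCTTGAAGGGCTCACACATGCCAGGATGCTCTCAATCCTGATGATGCTTAGCTCATTTAGCTGCGCTTGCATGCTCCCAGTCTCACGGGAGTGTGAACTCTATGCCTCGCATTACACTAAACATACACGCCGCCGCCACGCCCAGAATAATGGTTATATTAGGAGGACCAGTGCTGTCAATACTCTGATAGTATGCCAGCTCGGTTCGACAGGCTCTGCTAGTTATTCGCCGACACGATCGTTAGTGGTCAATGAGTTAGCATTGGCGTTTCGGCGATGGCAGCTTATTAATCACGATTTTCTGTTAGACCGTGCAGTGGAAGGTGCTTGCATACATAAACTCCCTGGCAAATTACTGGCAATCCTGCTAATTAGGCTGGACAAAGGTATAGTTGTAAGCCATGTATACCAGATCGCTCCACCTGCGAGTGACCCTACACCTCCGTTATCAGTCTATGTCACACACAGCACCTATTTTCGTCGACGAGCTTCCTATAAAACATGCAACCTAATTAGAGGGTCAATGGGGGCGCTTCAGGGGAAGCCGGTTAGCGGGTCACCTTTATTGGCGTCATTGGATCACGGCAGGTCAGATATTCACTGGGTAACAACAAAAAGGGAGCGAGCCGGAGCCTCACTCAACACTATCACCTCGCCTCCTACTGGTCGCACCTCTCAGGCGACTTTGAAGAATGTAAAGTCGAAGTATCGCCCTGGCACGAATGGGTTACTTCTCAAGGTAGGGGTCATGTTCATTTGGTTCTTGATA
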