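>dolphin
TTTCTTGCGTTCTTCGAGAATTCTAGAACTTCGTGCCCTCTACCTATCTCCGAAACAGCTATCTGCAGTCTAGAACTTATAACCGGAGGTACTGAGACAATAGTAAAAGTGTTTGCTTACGCAGGTGGGACATACACTGACGACCATGGCTTAAATCATACTGCAAAGAAGGCCACTCAGAGTGGGTCAGTTTACAGAAAACAGGAGTCGCCAGTCGTTCGGCAGGGCGGAACTTGCAGCGATTTAACACGTCATGAGGACTCATTCCTTGTATGGTGCCTCTGGTTCTCAGCAACGAGTGGCATAATGCATTGGGGAAATCTCCGAGTTCTACCCGTAGCACCAGTCTATTTTGCGAAGAAGCTGAGAGCCCCCACCTGTAGGTACTTTCGGGAACCCGGAAAAATGGCCACCTTGGGTGTTACTCAAAGCCCGGTGGAGGGGGTAATAACAGAACCTACTCACTTACAACTGTCTAATGCGTCGAACTTATCATCTGGAGTCCAAAACTGGCTGGTGTGGTTTATACTAACCCGGCGCAGAAGAGATGAATCAGAGTCTTCGTGGAAATCTAGACCTCCGATCCGGTTAAGCAAATTAACTACGGATCATCGGGGGGATACACAGTCCCCTGGATCCCCGTATACGTACCTCGACGCACGAACGAATCGCGAACCTATTTCATCGTGCCATGGCAACACCCCCACGGCGACGGTGGACGGACGGAGGTGGGAAGATCCGTGCCTAGTTTGTATGGGCTACGCATTGGTGTGCTCTACTCACATCAAACACTCCAACATAATAACATCTTCGCGGGTGGTACTAACGCACGGAAGGGTACTCCATACCCCACACCGTGCGGCTAAGGGGGTGATCGTCACGGGACCCTGGCGCATAAAGGAGGGGTTCTTCTTTTCTGACTCA
>whale
TTTCTGGCGTTCTTCGAGAACTCTAGAACTTCGTGCCCTCTACCTGTCTCCGAAACAGCTATCTGCAGTCTAGAACTTATATCCGGAGGTACTGAGACAATAGTAAAAGTGTTTGCTTACGCAGGTGGGACATACACTGACGACCATGGCTCAAATCATAATGTAAAGAAGGCCACTCAGAGTGGGTCAGTTTACAGAAAACAGGAGTCGCCAGTCGTTCGGCAGGGGGGAACTTGCAGCGATTTAACACGTCATGAGGACTCATTCCTTGTATGGTGCCTCTGGTTCTCAGCAACGAGTGGTATAATGCATTGGGAAAATCTCCGAGTTCTACGCGTAGCACCAATCTATTTTGCGAAGAAGTTGAGAGCCCCCACCTGCAGGTATTTTCTGGAACCCGGAATAATGGCCACCTTGGGTGTTACTCAAAGCCCGGTGGAGGGGGTAATAACAGAACCTACTCACTTACAACTGTCTAATGCCTCGAACTTATCATCTGGAGTCCAAAATCGGATGGTGTGGTTTATACTAACCCGGCGCAGGAGAGATGAATCAGAGTCTTCGTGGAAATCTAGACCTCCGATCGGGTTAAGCAAATTAACTACGGATCATCGGGGAGATACACAGTCCCCTGGATCCCCGTATAAGTACCCCGACGCACGAACGCATCGCGAACCTATTTCATCGTGCCATGGCAACACCCCCACGGCGACGGTGGACGGACGGCGATGGGAAGATCCGTGCCTAGTTTGTATGGGCTACGCATTGGTGTGCTCTATTCACATCAAACATCCCAACATAATAACATCTTCGCGGGTGGTACTAACGCACGGGAGCGAACTCCATACCCCACACCGTGCGGCTAAGGGGGTGATCGTCACGGAACCCTGGCGCATAAAGGAGGGGTTCTTCTTTTTTGACTCA
>hippo
TTTCTGGCGTTCTTTGAGAATTCTAGAATTGCGTGCTCTTTACCTGTTTCAGAAACAGCTTTCTGTAGTCTAGAACCCATCTCCGGAGGTACAGAGACAATAGTAAAAGTGTTTGCTTACGAAGGTGGGACATACACTGATGACCATGGCTCCAATTATAATGCAAGGAAGGCCACACAAACTGGGCCCGTTTACAGAAAACAAAAGTCGCCCGTCGTTCGGCAGGGCAGAACTTGCAGAGATTTAACGCGTCATGAGGACTCATTTCTCGGATGGCGCCTCTGGTTCTCAGCAACTAGTGGTATAATGCATTGGGGAAACCTCAGAGTTATTCACGTATCACCAGTACATTTTGCGAGGACGTGTAGAGGCCCGACGTGTAGGAATTTTCGGGAACCCACAATAATGGCCACCTTGGGTGTTACCCAAAGTCCGGTGAGGCGGGTGGGAACAGTACCCACCCACTTACAACTTTCTAATACGTCGAACCTATCGTCTGGAGCCCAAAATCCGACGGTTTGGTTCATACTGACCCGGCTGGGCAGAGATGAATTAGAGTCTTCGTGGAAATCAAGACCTCCGATCGGGTTAAGCAAATTAGCTATGGATCAGCGACGAGATAAAGAGGCCACTGGATCTCCATATAAGTACCTTGACGCACTAACGCATTGCGAACTTACTGCATCGTGCCATGGCAACACTCCAACGGCAACGGTGCGCGGACGGCGATGGGTAGATCCTTGCCTAGTTTGTGTAGGCTACGCATCGGTGTGCTCCATTCACATCAAACACTCCCGCAGCATAACACTTTCGCAGGTGGTACTAACGCACGGGAGCGAACTTCGTACCCCACACCGCGCGGCTAAGGGGGTGATTGCCACGGGTCCCTGGCGCATAAAAGACTGGTTCTACTCCGTTGACTCA
>pig
TTTTCAGCGTTCTTTGAGAATCCTAGAACTGCGTGCCCTCTACCTCTCTCGGAGACAGCTATGTGCAGTCTAGAACCTATATCCGGTGATACTGAGACAATAGTAAAAGTGTTTGACTATGTAGGGGGGACGTACACTGACGACCATGGCGCGAATCAAACCAAAAGGAAGGCCACACAGACTGGGTCTCTATACGGAAAACGCGAGTCGCCAGTCGTTTGTCAAGGTGGAAATTGGAGAGATGTAACGTGTCATGAGGAGTCATTTCTCGTGTGGCGCCTCTGGTTTTCACAACCAAGTGGCATCATGCATTTCGGAAACCTCCGAGTGCTACACGTGACACCAACACGTTCTGCGAAGAAGGGTAGGGACACAACGTGTAGGTATTTCCGGGAACCCAGCAAAATGGCCGCCTTAGGTGTAACTCAAAGGTCGGTGAGGCGGGTGAGAACAGTGCCGACTTGCTCACAATTGGTCAATAGATCGATTTTATCGTTTGGAGCCCAAAACTGGAGAGTGTGGTCGATTCTAACCCGGCCGGGCATAGATGAACCGGAGTCGTCGTGGAAGTCTAGACCTCCGATCGGGTTAAGCGAATTTACGATGGACCAGCTCGCAGAAGAACAGTTCACTGGATCCCCGTACAAGTATCTCAACGCACGAACGCATTACGAACTTGTTTCATTCTGCCACGGCAACACTCCTACGGGAACTGTGCACGGACGCCGATGGGTAAACCCGTGCCTAGTTTGTCTGGGCTATGCTTTCGTGTGTCTAGTTCATAGCAAACACTCCAACGAGATAACGCTTCCGCAGGTGGTACTAACGCGTGGGAGCGAACTGCATACCCCACACCGCGCAGCTGAGGGGATATTCGTCACGGGTTCCTGGCGTATAAAGGAGAGGTTCTTCTTTGATGACTTG
>camel
TTTTCAGCATTCTTTGAGAATCCTAGAGCTGCGGGTCCTCCGCCCCTCTCGGAGACAGCTATCTGCAGTTTAGAACCTATTTCCCGAGATACTGAAACAATAGTAAAAGTGCTTGTCTATGCAGGGGGGACATACACTGACGACCATAACTCGGATCCAACTAAAAGAAAAGCCACACAGACTGGGACACTATATAGGAAACGCGGGTCGCCGGTCGTTTGTCACGGCGGGACTTGCACAGATGTCACGTGTCACAAGGAGTCATTTCTTGAGTGGCGTCTCTGGTTCTCAGTAACGAGTGGCATCATGCATTTCGGAAACCTCCGAGTGCTACTCGCGACACCGGCACGTTTTGCAAAGAAGAGTAGAGACACTATGTGTAGAGAATTCCGGGAACCCAGCAAAATAGCCACCTTGGGCGTGACGCAAAGATCGGTGAGGCGGGTAAGAACAATACCAACTCACTCACAACTATTTAATAAGTCAAATTTATCGTCTGGAGCCCAGAACTGGACGGTGTGGTTCATTCTAACCCGGGCTGGCATAGATGAATCAGAGTCCTCGCGGAAGCCTGGACCTCCGATGGTGTTGAGTGAATTAATGATGGATCAGCGCGGTGGAAAACAGTCTCCTGGATCCCCGTACAAGTATCTTGACGCACGAACGCAGTGCGAACTCGGTTCATCGTGCCACGGCAACACCCGGACGGGGACAGTGTACGGACGGCGATGGGAAACCCCGTGTCTGGTTTGTGTGGGTTACGCTTTCGAGTGTTTTGTTCATAGTAAACACTCCAACGCCATAACTCTTTCGCAGGTGGTGCTAACGCATGGGAGCGAACTCCATATCCCACAACACGCAGCTAAGGGTGTAGTCGGCACGGGACCCTGGTGTATAAAGGAGGCATTCTTCTTCGGTGACTCA
>cow
TTTCCGGCTTTCTTTCACAAGCCTAGAACTGCGTTCCCGCTACCTGTCTTCGAAACAGCTATCTGCAGTCTAGAATCTCTGTCCGGTGATACTGAAACAATAGTAAAAGTGTTTGCCTACGTAGGAGGGACATACACTGACGACCACGGCTTTAATCACACTGTAAGGAATGCCACTCAGACTGGGTTACTTTACAGAGAACGCGAGTCGCCAGTCGTTTGGCAGAGCGGAACTCGCCGAGATTTAACACCTCATGGGGAGTCATTTCTTGTGTGGCGCCTCTGGTTCTCAGCAACGAGCGGCACTATGCATTGGCGAAACCTCCGAGTGCTACACGTAGCACCAGTACATTTTGCAAAGAAGGGTAGAGCCCCGACCGATAGGAACTTTCGGGAAACCAGCAGAATGGTTACCTTGGGTGTAACCCAGAGTTCGGTGAGACGCGGACGAGCGGCACCTACTCACTTACAACTGTTTAATACGTCGAACTTATCATCTGGAACCCAAAACCGGATGGTGTGGTTCATACTCACCCGCCTCGACAGAGATGAGTCGGAGTCTTCGTGGAAGTTGAAACCTCCGATCGGGTTAAGCAAATTGCCGATGGATCTGCGAAGAAGGAAACAGTTCCATGGGTCCCCGTACAAGTACCTTGACGCACGGACGTATTACGAACTTATTTCATCGTGCCACGACAACGTTCCCACAGCAACGGTGCACGTACGGCGATGGGTAAATCCGTGCCTAGTTTGTTTGGGTTACGCATTGGTGTGTTCTGCTCATATCAAACACTCCAGGGTTATAACACTGCCACGGATGGTACCGACGCCCGGGAGCGAACTACACACCCCACACCGTGCGGCCAAGGGGGCTATTGTCACAGGTCACTGGCGCATAAAGGAACGGTTCTTTTATTTTGACTTA
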