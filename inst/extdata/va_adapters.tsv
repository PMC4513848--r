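name	sequence	note
VA1	CCCCTTAGGTTGCAAATGCTCCGTCGACGGGATCTGTCCTTCTCTGCCGGCGATCGT	left_arm_terminus
VA2	TGACGCTTGGATGCGTGACCCCGTACGTCATGACCCGTCATGGGTATGTAAGCGAAG	right_arm_terminus
VA3	GGAGGTACTGGCCTAGCGTCGTGGCCCGGGAGAGACAGTTTAGTAGTGACTCGCGGC	
VA4	TTGGCGTTAATTGTAGCTTATTTCCCGCCCTGTGATTGAGGCGGGATGGTGTCCCCA	
VA5	GACTAAGACTCTGGTCACGGTTCAGAAGTGGACGATGCATGTCGTCGGGCTGATAGA	
VA6	TGCACGGCGCTAGGTGTGATATCGTACACTTGGGAGAAGTCAGATACGATTGCGGCT	
VA7	TAGCGGCGCCGGGAAATCCAGCATATTCTCGCGGCCCTGAGCAGTAGGTGTCTCGGG	
VA8	GAGTCTACGTTACACCTGAACTCGCATGTCTGGGGTTGTGGTCAGGCCTTGTCAATT	
VA9	GCGTACTGGCCGCCCGGGCCTGATGTGGCCGTCCTATTAGCATTGTACACCCTCATT	
VA10	CTTGAATCGGCTTTAGGATCCGGTACTGCCGACGCACTTTAGAACGGCCACCGTCCT	
VA11	GCAAGTTTTGAAGAGGTGTAAACTCTCCGCAGCACCTCCGGACTATGCCCGAGTGGT	
VA12	TGAAGCTACGCGCCGAGCGTCTGACTCCTTTAGTCCGCGTCATCGCTTTGAGCGCGT	
VA13	TCCGGATCCCTTTCGGTCCATATAGCGGATTTCCATAGACGTAGACCGCGCCAATGT	
VA14	GACGACGCGTTCTGTGTCTTCGTTGCGGCTCTGCGCTTGGTCGTTGGCGACGGCCGT	
VA15	TGTAAGGGCGTCTGTTAACCCAAGGTCCCTCGAACCGTATGCAGAGCCGTGGCTACG	
VA16	TATCGCGGGTGCGTGCATCGACAAGCCATGCCCACCTTCTGGTCGATTGGGCTGGCG	
VA17	CATCCATCGATATTTGGCACTGGACCTCAACGCTAGTGTTCGCGGACTGCACTACCT	
VA18	GATTAAGGGGCATACCGTGCCTATCCTGGTAATTGTGTAGGCTACCTGTCTGTATAC	
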