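target	shrna	species	designed_by	top	bottom
HDAC1	sh1	Human	SplashRNA	GATCCGAGGTTAGGTTGCTTCAATCTAATAGTGAAGCCACAGATGTATTAGATTGAAGCAACCTAACCGTGGGCC	CACGGTTAGGTTGCTTCAATCTAATACATCTGTGGCTTCACTATTAGATTGAAGCAACCTAACCTCG
HDAC1	sh2	Human	SplashRNA	GATCCGACACAGCGATGACTACATTAAATAGTGAAGCCACAGATGTATTTAATGTAGTCATCGCTGTGGTGGGCC	CACCACAGCGATGACTACATTAAATACATCTGTGGCTTCACTATTTAATGTAGTCATCGCTGTGTCG
SMAR4A	sh1	Human	SplashRNA	GATCCGATGGATGTCAAACAGTAATAAATAGTGAAGCCACAGATGTATTTATTACTGTTTGACATCCAGTGGGCC	CACTGGATGTCAAACAGTAATAAATACATCTGTGGCTTCACTATTTATTACTGTTTGACATCCATCG
SMAR4A	sh2	Human	SplashRNA	GATCCGACCGTGGACTTCAAGAAGATAATAGTGAAGCCACAGATGTATTATCTTCTTGAAGTCCACGGGTGGGCC	CACCCGTGGACTTCAAGAAGATAATACATCTGTGGCTTCACTATTATCTTCTTGAAGTCCACGGTCG
MTA1	sh1	Human	SplashRNA	GATCCGCTCAAGTAATTTTCATATTAAATAGTGAAGCCACAGATGTATTTAATATGAAAATTACTTGAATGGGCC	CATTCAAGTAATTTTCATATTAAATACATCTGTGGCTTCACTATTTAATATGAAAATTACTTGAGCG
MTA1	sh2	Human	SplashRNA	GATCCGAAAGGTGCCATTTTAAATTTTATAGTGAAGCCACAGATGTATAAAATTTAAAATGGCACCTTCTGGGCC	CAGAAGGTGCCATTTTAAATTTTATACATCTGTGGCTTCACTATAAAATTTAAAATGGCACCTTTCG
MTA2	sh1	Human	SplashRNA	GATCCGACAGCATAGTCCAGTTTTATTATAGTGAAGCCACAGATGTATAATAAAACTGGACTATGCTGGTGGGCC	CACCAGCATAGTCCAGTTTTATTATACATCTGTGGCTTCACTATAATAAAACTGGACTATGCTGTCG
MTA2	sh2	Human	SplashRNA	GATCCGCACGCCAGTTCTCAGAAATAAATAGTGAAGCCACAGATGTATTTATTTCTGAGAACTGGCGTATGGGCC	CATACGCCAGTTCTCAGAAATAAATACATCTGTGGCTTCACTATTTATTTCTGAGAACTGGCGTGCG
FAS	sh1	Human	SplashRNA	GATCCGCAGTGTTTGAAAAGATTCTTAATAGTGAAGCCACAGATGTATTAAGAATCTTTTCAAACACTATGGGCC	CATAGTGTTTGAAAAGATTCTTAATACATCTGTGGCTTCACTATTAAGAATCTTTTCAAACACTGCG
FAS	sh2	Human	SplashRNA	GATCCGATCCAAGGATGTTTAAAATCTATAGTGAAGCCACAGATGTATAGATTTTAAACATCCTTGGAGTGGGCC	CACTCCAAGGATGTTTAAAATCTATACATCTGTGGCTTCACTATAGATTTTAAACATCCTTGGATCG
CD4	sh1	Human	SplashRNA	GATCCGACCTGATCATCAAGAATCTTAATAGTGAAGCCACAGATGTATTAAGATTCTTGATGATCAGGGTGGGCC	CACCCTGATCATCAAGAATCTTAATACATCTGTGGCTTCACTATTAAGATTCTTGATGATCAGGTCG
FAS	sh1	Mouse	SplashRNA	GATCCGAACAGTTAAGAGTTCATACTCATAGTGAAGCCACAGATGTATGAGTATGAACTCTTAACTGTGTGGGCC	CACACAGTTAAGAGTTCATACTCATACATCTGTGGCTTCACTATGAGTATGAACTCTTAACTGTTCG
FAS	sh2	Mouse	SplashRNA	GATCCGACGGGTTCGTGAAACTGATAAATAGTGAAGCCACAGATGTATTTATCAGTTTCACGAACCCGCTGGGCC	CAGCGGGTTCGTGAAACTGATAAATACATCTGTGGCTTCACTATTTATCAGTTTCACGAACCCGTCG
Tbx21	sh1	Mouse	shERWOOD	GATCCGCCACACACGTCTTTACTTTCCATAGTGAAGCCACAGATGTATGGAAAGTAAAGACGTGTGTGTTGGGCC	CAACACACACGTCTTTACTTTCCATACATCTGTGGCTTCACTATGGAAAGTAAAGACGTGTGTGGCG
CD4	sh1	Mouse	shERWOOD	GATCCGAGCATGGGAGAAAGGATCGTTTTAGTGAAGCCACAGATGTAAAACGATCCTTTCTCCCATGCCTGGGCC	CAGGCATGGGAGAAAGGATCGTTTTACATCTGTGGCTTCACTAAAACGATCCTTTCTCCCATGCTCG
CD4	sh1	Mouse	SplashRNA	GATCCGCACAGCATATCTTAATTCATAATAGTGAAGCCACAGATGTATTATGAATTAAGATATGCTGTTTGGGCC	CAAACAGCATATCTTAATTCATAATACATCTGTGGCTTCACTATTATGAATTAAGATATGCTGTGCG
CD19	sh1	Mouse	SplashRNA	GATCCGACAGTCCTATGAAGATATGAGATAGTGAAGCCACAGATGTATCTCATATCTTCATAGGACTGGTGGGCC	CACCAGTCCTATGAAGATATGAGATACATCTGTGGCTTCACTATCTCATATCTTCATAGGACTGTCG
CD127	sh1	Mouse	SplashRNA	GATCCGCGGGTAAGTTATTCAAATTCAATAGTGAAGCCACAGATGTATTGAATTTGAATAACTTACCCATGGGCC	CATGGGTAAGTTATTCAAATTCAATACATCTGTGGCTTCACTATTGAATTTGAATAACTTACCCGCG
CD127	sh2	Mouse	SplashRNA	GATCCGCCCATGTCTAGTTTTTACCAAATAGTGAAGCCACAGATGTATTTGGTAAAAACTAGACATGGTTGGGCC	CAACCATGTCTAGTTTTTACCAAATACATCTGTGGCTTCACTATTTGGTAAAAACTAGACATGGGCG
CD44	sh1	Mouse	SplashRNA	GATCCGCCAGGTTTGAGTTTATATCAAATAGTGAAGCCACAGATGTATTTGATATAAACTCAAACCTGATGGGCC	CATCAGGTTTGAGTTTATATCAAATACATCTGTGGCTTCACTATTTGATATAAACTCAAACCTGGCG
CD44	sh2	Mouse	SplashRNA	GATCCGAAGGGTATAAATTGATTCATAATAGTGAAGCCACAGATGTATTATGAATCAATTTATACCCTGTGGGCC	CACAGGGTATAAATTGATTCATAATACATCTGTGGCTTCACTATTATGAATCAATTTATACCCTTCG
CD90	sh1	Mouse	SplashRNA	GATCCGAAGGGCTGCTTCTGATTATTTATAGTGAAGCCACAGATGTATAAATAATCAGAAGCAGCCCTGTGGGCC	CACAGGGCTGCTTCTGATTATTTATACATCTGTGGCTTCACTATAAATAATCAGAAGCAGCCCTTCG
CD90	sh2	Mouse	SplashRNA	GATCCGCGCTGTCATTTTGTACTCTGTATAGTGAAGCCACAGATGTATACAGAGTACAAAATGACAGCTTGGGCC	CAAGCTGTCATTTTGTACTCTGTATACATCTGTGGCTTCACTATACAGAGTACAAAATGACAGCGCG
CD8	sh1	Mouse	SplashRNA	GATCCGCCAGTTCCTTTTTCTTTATGAATAGTGAAGCCACAGATGTATTCATAAAGAAAAAGGAACTGTTGGGCC	CAACAGTTCCTTTTTCTTTATGAATACATCTGTGGCTTCACTATTCATAAAGAAAAAGGAACTGGCG
CD8	sh2	Mouse	SplashRNA	GATCCGACTGTAGTAGAATCCAATTAAATAGTGAAGCCACAGATGTATTTAATTGGATTCTACTACAGCTGGGCC	CAGCTGTAGTAGAATCCAATTAAATACATCTGTGGCTTCACTATTTAATTGGATTCTACTACAGTCG
Pten	1524	Mouse	SplashRNA	GATCCGACAGCTAAAGGTGAAGATATATTAGTGAAGCCACAGATGTAATATATCTTCACCTTTAGCTGGTGGGCC	CACCAGCTAAAGGTGAAGATATATTACATCTGTGGCTTCACTAATATATCTTCACCTTTAGCTGTCG
Pten	932	Mouse	SplashRNA	GATCCGCCGACTTAGACTTGACCTATATTAGTGAAGCCACAGATGTAATATAGGTCAAGTCTAAGTCGATGGGCC	CATCGACTTAGACTTGACCTATATTACATCTGTGGCTTCACTAATATAGGTCAAGTCTAAGTCGGCG
GFP	sh1	N/A	SplashRNA	GATCCGAATGGACGAGCTGTACAAGTAATAGTGAAGCCACAGATGTATTACTTGTACAGCTCGTCCATGTGGGCC	CACATGGACGAGCTGTACAAGTAATACATCTGTGGCTTCACTATTACTTGTACAGCTCGTCCATTCG
GFP	sh2	N/A	SplashRNA	GATCCGAACAAGCTGGAGTACAACTACATAGTGAAGCCACAGATGTATGTAGTTGTACTCCAGCTTGTGTGGGCC	CACACAAGCTGGAGTACAACTACATACATCTGTGGCTTCACTATGTAGTTGTACTCCAGCTTGTTCG
GFP	sh3	N/A	SplashRNA	GATCCGCCAAGCAGAAGAACGGCATCAATAGTGAAGCCACAGATGTATTGATGCCGTTCTTCTGCTTGTTGGGCC	CAACAAGCAGAAGAACGGCATCAATACATCTGTGGCTTCACTATTGATGCCGTTCTTCTGCTTGGCG
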