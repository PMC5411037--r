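>H1|ATL|freq=15
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCCA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTACGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H2|ATL|freq=108
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H3|ATL|freq=4
ATGACAGGCCGGAAACCCCAAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H4|ATL|freq=1
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCCA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTACGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGCGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H5|ATL|freq=2
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAGGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTAGCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H6|ATL|freq=1
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGATCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H7|MED|freq=14
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATGGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCGTCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H8|MED|freq=49
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATGGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H9|MED|freq=1
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATGGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGTTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
>H10|MED|freq=2
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATGGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCGACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGG
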