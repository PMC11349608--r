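>TRBV1
GTGCCTACTGAACCGAGAGTGCGGGCCGTCGTCTTTACCTCTTACACGATAGTGTGCCTC
>TRBV2
GTAGGCCACCCTAAGCAGAATAGTTCGCGGCAATCTGGCGCGACCCTTCGCGAATGTGTG
>TRBV9
GTTTCACACTCACGCCTACTGCACTGTAAAAGAACCTGGGTCGTTACCTAAACGTGCTAA
>TRBV13
AGACGATAGAGGGAACTTCAATCTCGGCAGGCTAAGCCCCGCAACATGAATATATGTGCG
>TRBV14
CCGCTATACCGGTCCCAGAAACCGTGAACCAAGATCAGACGAGCTTCCTGAGAATGCCCC
>TRBV15
CCAATGAATTCCTTTCCAGGCCCAATAGTTTGAGAGACAACTGTTGGCCGTCCATGTGTG
>TRBV16
AAGAGCGGTCGGCCCCCGACCGATACGCCATGTGCGGAGAGAATTCATCTCATGTGCACC
>TRBV17
GGCCTCGTTGTTATGCGACGCTCGGTTGAGAACTCTCGAGTGGTATTTGACATTTGTACC
>TRBV18
GTCTTAAGGTATTACGACTGGGGTGTAGTGGATCTTTCTGCGAGCCGTGGCCCATGCACT
>TRBV19
TTGTTTAATTCGGATAGCTCTACATTGCGGCAAATCCCGCATAGTAAAGCCTCGTGTATT
>TRBV20
GCCCTGAGATCTAGTATTTATTCAGCGTACGAGCGCTGAAGAAGCTCTTTGCCGTGCATG
>TRBV21
AGTGTGACACTGTGTCGAATACGTATGGGCAACCGGATTGTCACGGTATTGCATTGTTAT
>TRBV22
ATGCGGAGCTAATTTTAACGCCACGAAAGAACCCTGGACTGGAGGCGATCAGAGTGCCTG
>TRBV23
TATGAGTCAGCTGGCCTTTTACTGCTATATCGGGTATCCTTGAGCTAAACGGAATGTGCT
>TRBV24
GATCGAGCTCTGGAGGTGTATATGGAGCTAGGAAGTACAGCATGGTCAGGAAGTTGCACT
>TRBV25
TATGTTCCCAACCTATGTACTTGAGGAGGGTACTGGTTTCAGTTGCATTGTCTGTGTAAG
>TRBV27
TTCTCCAGAGTGGCGTGCGCAGAACTAACCACCCGCCCCGTACGTGTCGGCTTCTGCCCG
>TRBV28
ATGCCTCAGACACTTGACTTAGGTGTAGTGAATAGCTAAATTCCAATATCAAAATGTTCT
>TRBV29
ACTCATCTTATGCTCTGGTGCTGCCCCGGAAAACATGTAGCCGACACTCCGGCATGCGGA
>TRBV30
ACCGACGATCACCGATCCCAGGGTTACCCCAAAGGCCACAGCCACTTGACGTCCTGTAAG
>TRBV3-1
ATGTGATCTCGCGAGTTAAATACAAACATCGCGTACACAATCCGACAGGACGCGTGCAAG
>TRBV3-2
ACGGGAGTTCACTATTGCGAAATTCATAACTAAAGTTTAAGAGGCAGAGTATTCTGTTAG
>TRBV4-1
AGACTGCTAACCCGGTTTGCATCGCCTCTTCGTATAAGGATCAGTGAATCTGGATGCCTA
>TRBV4-2
TAATCGTATTAGGTTGGTCTCGATTACTAAAATCTGGACGTAACGGACCGGCTTTGTGCC
>TRBV4-3
CTTGGCTACTTCAAAACTGTCACATAACATTCCTAATTAGTTTAACTTGGTGAATGCTGC
>TRBV5-1
TCGATGCCTCGCCGGGCTCGTAGGTGCTAGCACATTGGGACGAGACGATTGCACTGTCAT
>TRBV5-2
GATACTTATTAAGCCAAAAAGTCAGCCATATTACGTGTGTATTTACGCACTCCGTGCGTG
>TRBV5-3
TCCCCTAGAGTGGCAGATGTCGTTTTATACGATCCTTACGTGTTATCCTCCTGGTGTCCC
>TRBV5-4
GGAGCGGTATAGGACTCAGTTCTTTCCCGGGTCCTGCATGCTGAATGGAGTACATGCCCG
>TRBV5-5
TATATATAGGGAACCAGGGCCCAGTTGGCGCCGAACGGATTGTCTACCGAGCGTTGTGTA
>TRBV5-6
TCGCTTGGCCCGTAACTACCATAATGGCATGTGGTCACAGAACTGTTGGCGCGCTGCAAC
>TRBV5-7
GATATATAGGTCAGCGCCCTGGCCGTGCGTCACTGATAGTACGTCTTGCTCCTATGTGAA
>TRBV5-8
GTCTTCCGGGCTGTAGTGACTCTAATTTTCAGCTGCTCCGTGCTCCGCTCCGACTGCACT
>TRBV6-1
GAAAACGGATACGCCATCCGGCAACATGATAAAGAAATTTCCCACCCAACTAGGTGTAGT
>TRBV6-2
ATTGTTTCAGGTGTTCCGGCGTCTGAATGACACTCGCGACTTTGCCTGTAATATTGCTGG
>TRBV6-3
TCCCTGGCGTACCAGGTATTGACCGGCCGAGCTAATTAAATACGGCCCCCGCAATGTCAT
>TRBV6-4
GTGCTCATTCTACAGTCTATACCCGGTCCAACTTCCTCCGGTGACTTTCGCTCGTGCCTG
>TRBV6-5
TTTCATGAGATAAGTGTCTTAGTCCGGGAGCGTCGGGCCTTCCTAGGTACGTTTTGTAGT
>TRBV6-6
ACTGAACACCTGTCCTACTATCGGTTAACATGGGAGCACTTGTAAGACGCCCTGTGCGAC
>TRBV6-7
ATTGCGAACCGCAACTTTATTTATGTCTCCCCCGCGTTTTGCCAGAAACGTTTGTGTTAT
>TRBV6-8
AGTACCTATATTCGTTTCTACACACGATTACCAGGCGTGTCCCGAACTGCAAGGTGCGCG
>TRBV6-9
CGTCGTGTATTTTATGGACTGCAGCACGTTTCACCCCCAACACTTACCCCACTCTGTCGC
>TRBV7-1
GCAAGTCTCTACCTTACCTGTCGCCCAACCGGAAACAGAGAACGCGCTATACATTGCGAC
>TRBV7-2
GGGTATTACTCTTAGTCGAACCTGGAAAGTCTCAGAACCCGAAATCGCTACATATGTGGG
>TRBV7-3
AAGCAAAGTGTGTTGGGCATCGGCACCGAACCTCAAGTACATGACGTCAATACGTGCAGA
>TRBV7-4
GTAAACACCAGACGACCACGCACAAAGGGGGTGATGATCAATTCAAAGAGAACGTGTCAA
>TRBV7-5
GTAAGATGGTAAAGCCTTCAGTAACAGGGCTCGTGCGAATGAAACCACCGTATATGCTAT
>TRBV7-6
TGCGTCTATGCGGGTTCAAACTGAATTCAATTCGAGTTGGTCTATCGAACGGGCTGTCGC
>TRBV7-7
GGGGTATGCATCCCTAACCTTCTTCAGTTCCGACCAAGGCTTCAGTGTCCTTGCTGCCAT
>TRBV7-8
CGTTACTGGCGATAAGACCCTAACGCATCATGCGTACACAGAATAAACGAAATCTGTGAC
>TRBV10-1
TCGGGCCATGGACTCGAACACTATTGCCATGAGGAGTTCCCTGTTACCAGTAATTGCCAA
>TRBV10-2
GGCCTGAGATATCAGTGGCGCGCCGCGGAAGGTCAATTCGGGTCCTGTATACCCTGTATG
>TRBV10-3
GCAAAAGAGCCAGAACTGCACCCTGTAATGTCTTTAGAACATAATAACTTACGTTGCCGT
>TRBV11-1
TAAGAGAACCTGACAGTTGACCCGCCATCCGGCAACCCTAGGACGTGCTGAACCTGTTCG
>TRBV11-2
TGGATAAATGCGGCCCAGATAACTTTCATATCTAGCGGAGGCAGATCGGTGGTGTGCTTA
>TRBV11-3
CCAAGGTATGGGTAGTGGCGTAAGTACTTCTAGGGAATAAACACGACTCTTGTATGTGAC
>TRBV12-1
ACATGGCAAGATGCGCGATGTAGCGATGACCGACCAATTGACTACGACTCACTCTGCGGT
>TRBV12-2
ATCGTCACCGGCGAGGCTAACCTGCAGAGACTCATGATTAACTCGGTTATGTAGTGTCTG
>TRBD1
GGCACAGGGGGC
>TRBD2
GGGACTAGCGGGAGGG
>TRBJ1-1
GCCCTTAGGTTCTAATGTTGTAAGTCTGCAGTTGGAGCTATGAATTAC
>TRBJ1-2
ATCATCCAATTTACCCCTACCGACACCACTTGTAACGGCTGTCTACGT
>TRBJ1-3
CTCGCGTACTTCGCAGCGACGACGGTCAAGGGGCGCCAGCAGCGACTC
>TRBJ1-4
AAAATTCGTTTTGAATGCTACTGATTATTTGCATTCCCCTGTACAGCG
>TRBJ1-5
TTAGTCGTATTCCACCGTTGGGCACCCGTTTACCCGAACTTTCGCGAC
>TRBJ1-6
GACACCGCGTTTGGCGGGTATCGATTCTATAAACCTTCGCCTGGGACT
>TRBJ2-1
CCTGTCCATTTCCACCAGTCCTGCGGGTGTGTTGTGTGCTGGTAGCCT
>TRBJ2-2
TTGCGCAGGTTTTTGCGCACAAACATCTTGTAGGCACTGCAAACAGTA
>TRBJ2-3
GTGTTTTCATTCCGCGGTACCTGGGGTTATAAATTTACTGTATGAAAA
>TRBJ2-4
AGACGCGGTTTTAAGTTCCGAGGGGGCCTAGTCGGGACACGCCCGCCC
>TRBJ2-5
TGTCACTGGTTCGTGGACCGGCGGCATTTTGATGCGACATAGCACACT
>TRBJ2-6
TCACCTCGTTTTATTGCAAAAGAATTCACCAGGAGGATACCGAACGTG
>TRBJ2-7
AGTGTGACTTTCGTGCCGATGGCGTAAGGCGCGGCTGACTATTCCGTA
>TRBJ2-2p
GGTTTTCGATTTGACCCAACCTCTTAACTCTATTTGCAGCTGCAATAA
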