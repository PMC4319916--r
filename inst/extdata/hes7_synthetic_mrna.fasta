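>HES7_synthetic synthetic HES7-like mRNA (stand-in; see ?synthetic_hes7_transcript)
GAATCCTCTGGAACTGGTTCTCGGACTAATGATTGGTCCACGACTTCCTTCGGGCGGATGTAGCGACTGG
ACACAGTACAACTGGGAAGAAGGTCTTACTATGGATGTCCGGGTGGTATTTACTTCAATGCGTGAGTGGG
AGACACCATATACAGCTGGCAGTAGTCGAATTAACCGAAGATGCCCCATACACCATACATTCCCCGTTTT
CACAGTTATTGGGCTGACCAGTGAGGTTTCTTTATACCGCCCAACGCGAGAGAGGCGCTGTCGCCCGCGT
GGTGGCGTTGGCGACCTAAAGAATCCGGGATCAATCCTTGAAATTAATACTTATAGAGTTGTATATCTGA
TTAGCCGATGCAGCGAGCGTAGGAATCCCTCGGGAAGTGCGCCAGACATTCACCGGCTCCGGGTGCTGAA
TGCCAAAAGCACCACGGTTGGTGGCGCCGCCCCACGTAACTCCATTGAGGGTAGGCGTCAGTGTGTACCT
GTACCCAAGCACATCCCGTATCCTCGACATACACTACGCCAGCCAAACGCAGAATATGTTAGTAAGCGCT
TCCGGACCGTCACCGTCCTCATAGCTATCACATGTACCGGTGTCCACAGCAATCGACCGACTCCCATCCT
TACAAATAGTTCCATGTCGCAGTCTGGCCCCTGTGGAAAGATTGGCCAGATAAATCCTATAGTGTTCCAG
GCATTTAAGGGACACGTAGATGGGAGCGACTCAGCTTCTCCAATGATTTTCGTCACGCCTCATCCTATAC
GGTGACTACACTGCTCGGGATGGCTTAAATTGACAATCTAGGTGGCAACGAGCGAGTAGGCAGGTTCCGA
CTCCCAGGTTGCGAGAGCTTGTAGTCACCTACGCAGCGACCGCACAGGTACCCCACCGACGTTGGTGGCC
ACGCGCCGGAGCCGGGCCCTCCGGAGAACGTTTCTTCCTGAATCAAAGTAAGAACATGGTGTCGAATATT
AAGCGTGACTGAGACCGTGGAGGAATTATCGTCTCTCTAGTTAGCCTCCGTTCGCGTGTAGGGTCAGTGA
TGAGATTGGTACTCAGTGAGGTTCT
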