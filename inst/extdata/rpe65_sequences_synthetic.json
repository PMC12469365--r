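{
  "note": "SYNTHETIC stand-in sequences: consistent with every printed reference residue/nucleotide and the printed frameshift consequences, but NOT the RefSeq RPE65 sequence.",
  "cds": "ATGTTGAGGCAGAAAAATAAAACCTGCTCTACAGCAGACCGACCTACCGATTTGGCAATCTTGATATCCTACACATTTTTCTCAGTTAAGCAGGATCCGATGCAAACCACGGGATATCCCCACTGGGGCTGGCATCTTGCGTCCGGAATACTTATAGGGCAAATGTTGAGCCGGCCGCTTGCGCCTCGAACGCGAACCTTATCTCCCCACATGAGGGGCGGCGCGGTCAAAGCTAGCTTGGTCAAATTTATCCGCGTTGATAGCTACGTTCCTAAAAGCAGGGAATATCGGATCGTCTCGGTAGAATGCAAGCTAAGTCGGAATCCAGGGCCGAAGGATCGGTTCATGCCTAGGTTTTCGTCGGAATTGCGAGGACCAATGAAGGGTCAGATTACCTCGTACCCGGTCTTATCCGTGAGCTGGGATTTGACTCCACGTGCAGAAACCAACCAACACTACGATAGCTATATAGCACAAAGTTTTACTTTACAACAAGTTCGTTACCGCGGTATACGCAACGGTGTATGTCTAGGTAACCTTCGTCGGCTGTACTGGCCTATAGCCAGGTATCACATTCCGAGAATCCTATATACTCATTGCATAAGTCCATACGATGATTATGAAGCGTTATCAGCGACTTTGGATCTGGAAGATGCCCATTCCTTTTGGGAGATCGTTACTTGTCTACGCGGGCCCTTCCGAGAGAAGTTTTCTTACGTTCATCTTTCTGCGCTAATAGGGCCACAGGTCAGCCACGACGTACGTGTCTCACTTTATAAAAATACACGGACTCTTGAAGTCGTGTGCAATACAAGCAATCCGCTGAAAGTCGATGCAGCCTCCGTGTACCGGTTCATGGGAGAAAAAATCAGTCGTAAATTAGAAGACTCAAATGTTCCCCTCACTTACCAAGAGATCGCTAACGACCAACATGGGAGGAACTTGGGTCAATCGAGCAAGTTGGGTGATTTACGAAAAAGTACTTGTTTTAGCCAAGGATTTGGCAGCTATCTAGTTTACGGGGGCTTTGCTAATCAGCGTTTTTCACTGGAAGCAGTTAGATGTCAGAGAGACTCAGAAGTCACAATGGAAGAGACGTCTGGAATTGCTGATCATAATACTGACTGCACTGCAATCCTCCGGTTGGTAACGCAACCAGTTGTCGAACCCTTTCCTCAGACTCGGCATGCTATATCGCTACACAAGACTAACACGCAGCTCACCACGTGCAGGCGTGACTCTGCTTTTCTCCCTGGAGAATTACCCTACGCTGGGATTACAGACACCGTCATGGGGTATGCGTTCCCTATTCCGCATTTTTCGTTGATTTTAGATATTCTTTATAAGGTAAAGCTAAAACCGCGATGTATCCGGGTCCATTTGGGGACCTTCGGAGGCAAGTTGAATTTTGGGACAATTGAGCATAGGGGATTCAAGCCCGCCCGGGATTCCGTTCCGACGCATTTAATCGGTCGAGCCGACAGATACGCTGTCCCTGGCCACAGAAGGAGACGCGTTCATGCGGAAGCAATATTGCAAATCTTGGAGGGTTGTTGCATTGTATCGGCGCTGAAATTGAAAAAGATTCGAGCATATTCTTAA",
  "introns": {
    "1": "GTCCGTAGTCCTGATTGAACGTTTGAGATTGCAATGTGCCACGTTTCTTGGGTTGCTGTCGTCAAATATGAACGACGTGAGAGGGCGTAAAGGTCGTCGTTAGGTCTTCGGCTATTTCGAAAGTGTATCGTCCCATAACTCGGCGCGTGCAGCGATTCCACATCCCAGAGCTGGCCATCGTCCCCTAGTTGTGACTATCAACCTACGACTATATATTCAGTTCCTACACGGGCTGTTGAGAATGAGGTACCCTGTTGTAATAGCAAATCGCTGTATGGCGGTATCCTTCGAGGCATAGTCTCTTCAAGCTCGGTACTAAGAGCCCGCGGTGGATTATTCGCAACTAATACAAGTGTAGTCGCAGTGCGCCATTGTCGGGAAATGCCCGACAAGGAGGTAG",
    "2": "GTTGTCGCTGTGTATATGCTATGACCCAAACACTTGGAAGGGGGCGTGAGGTTACTAGACTTGCCAACCGGGAGTCCAGACGGAGATTTGAAGAGTATTGGAGAGATCTTCGGAACGGGAGCCCTACCTAGGGAGTGTGACTCCGAGGAGAAATATTGCCTTACGAATCCGTCGTAGGATTATCGTGTGAGCGGTATACCTCGAAGAACGCAGACGAGGCAATAATGTCCCTGCATAGACCCTGGCACCGCGTCGTGTTGCGGTACACGTAGACAAGAGTTGCTTCACTGCCTCCTTTAGTACCCGAAATGCTGCAGAATGCCCAAAAATTAATAGAGGGCTCGCTTCTTTATTCGAAACACGGATTATTGTAATATCGAGAGGCACTCATCGAACGGAG",
    "3": "GTCGCAACGCTAGGGTGACGCTCCCTTCGAGTTTCAATTGGAACTATTTTACCAGATTACTGTTTCGACCTGAGAGGCCTTCACACTCCTCATTCTTAACACGATCATATAAGCTACTTCGATCAGCACCGTTAGGTGTCAGCATATATGAACGAGGTATTTGGGGCGGGACACCGTCATAACTGGCCCGATCCGGCCCGTCATGTCGCCGGGTACTTCGATTACCGTCCTCATCTAAGCCAGGCACGTTGTTAGCGTCCGTGCTGTGTTAACGAAATGGACAACCGGTGCTATCTGGGTAGCCCCTGGTGCGAATTAAAAGGAAGTACATTGTGGGCGATTTATACGTGTGTGCGCCCCCTACACAGTTAACCACTCGTGTCGATTGCACATGTATGAG",
    "4": "GTGTAATATTCATGGTCCTTATGAGGTAGCTTGAAGTCTCAAAGTGGCTCGTGCTGGATACACGACTGAATCTTCCTGAGCATGCATTGCTACGTATTAGATGCGCCAATGTCTGCTAGTTCATTGAGCTTACTGGGGCTTTGGGTCCTCATCCCTGCTTAGCCATTGCCGTGCCGTTAGATCTTGAAAGCAAGCTGCAAGTTCGTCTGACCCTAAGGGAGTCGCGTCACTCTATAATTGATCGAATAATTCAGTGCCTGACCAACCCTCACGCTTAGAGGTTTCCTACATAAGCATAACGAGACGGCGGGCGATGGGAGAATTAATTATCTATGTCTGTGAGTCGCCCTGGGTCTGTCCCTAGGCTACTCGGTTAGAGCGGCAATCCAGGCACGAGTAG",
    "5": "GTCCCCTCTCCTTTATAGTTGTTAATAGGGTGGCTAGGCGATAACGGAACCAGATCGGATTGGCGCCACACACGCTATCACATAAGCCGAGGTTTATGACGATCGAACGTGAGAGCAGATATGTCGCTGTCCGTGAGGCTTCCCACCACCTTTAAGCTTATGATGGTGGCTACTCACTAAGCTCCCTTATAGTTGGAATCCGGCTTATAAGGTTTCGTGAATTCATCACCCATTGGTGTGTCGACAGCGCCGGGAGAGGTTACGCGGGCGAAGGCTTATATCGGGCTGCATTTTCAATACCAACCTGGTGTCGACATCATGATGTCATCTCGCGCGACTGAATTCCATACGTTCCCCGCTACTAAACTAAGGCAACGTCAACTGGGAGGCTATTAATGAG",
    "6": "GTCTTGGCGTATAATATCAGCAAATATGGTGCTACAAGATGGTGTGAGGGCACCTGCCAGACGTTGGTTGAGTATCTCTGTTTTGGTCCGCCTTCTCGTCACTTGAGAGAGTAGTTTTGAAGGCCGCCCAGGCGTTCAGGAGAGGCAATCGTATGCAGGATGTAAAGCACCGTCCAGGGTTTTATCCGAGAATCCTGGAGAGCGCTCTCACTGCGTCCCGTTGAAGCGGTGGGCAAGTTCTCGAGCATGCCGCGATAAACAATTGAGTCCCATCTCGGGTAGTCGAGTGTCCTTATGATTTGCCAGATCTATTTTGTTGGTAATTAATTGAGCCCGCACGGACGGGGTGATTTGGTTAAACTGGAACGCGCGATAGGAGGTATAGATCTGTGGCCCGGAG",
    "7": "GTCCCGATAGTTATGTCTAGAATTACCATCCTGCCTAACCTGTCAAAACCATGCTATGTCAGGTAGTTTCCCACTTGCCCAGAACCTCATACGCTCGAAATCATGACCTCTGCCTGTGCCGTGCTGATTTATCAGCAGTTTTCCGGTCCGGTTCCTCGCCTCGCAGAAGGAGATACTTTCTTTATTTGTGCGAATTTTCGGGTGGCCCAGCCACGACCCTTCACGTGAAGCTGGTGTGCCACTTTCAGCTTTCCGCTGTATAACCTGCTCTCAATAGACCGCCTCTATAAAGAAGGTTCTCAATAGAATACGACGTTTGACGGTTAAAGTCTACCTAAATCCGACCGTAAATGGGTGCGCCGTCTCGAGATGAGGCCAATCCGTTGGCCTTCGGCTCTAG",
    "8": "GTCACTAACCCCGTTTAGTGCCAAATGATCTGAATACGTAACACGTGGCCGCTGGCGGACTTGATCATTGCATCAGTTCGGTAAGGCGAACGATTATCGGCGTCACCTCCGTGAGAACCGACGATACTGTACACATGCGAGTACTGTACATCACTTCCTAAGGAGAGATTGGGGGATATGGGTAACGAATCAGGTGTATTATTCAGTTCTAATAGCATATGCTAAGGCCGAACCCATAACTGGTCTCATGCCCAATTAGCGCAGAGATCAGTGCGGCGCCCGGTATATTCCACGTTCAATGTTGTTACTGGGAGGCCCTTCATGTCGGAGGCTGAATAGGTACAAGGCCTCGGCGACCTCAGTGCTTACCGGTTGTATGCCCTAAGGACCGAAGGGCCAG",
    "9": "GTTTTTTCAGTATGCCCCTAGATATTAAACGCACTCCATCCAAGCCGAAGCACAACTTCGGCTGCTCAGCTCAGGGCCGACATCTGACGTGCGCACTTTCTAGAACAGCCCCGCTCAGTTACTCCCCGAACCCCTGAGCCCACAATAACGACGTGGCTGGACAAAGGTGAAGTACATCATAGACCGACGAGGACTCATTCTCTACTATAGTGTTTAGACCCCAACCGGCCTGTAAGAAGCATGTTCTCGCGCTAGAAGTAAGACCTCGTTCATCTCGCCTGGGGCAATGCCTGTCGTTTCTACATGCGGTAGCCCGAACACCCTAAGCGAAGGACCCGTTTATAAGAGTCCTACTAGTGCTGCCACCCAGAAAAATACACCGAATTGCGTAAGCTCAAAG",
    "10": "GTAAGGAAAATCGCATAACTCCGAAGTCTGCATCCTTAAAAATATCCCTCAGCGCATAAATCTCCCTGCGCGGCCACTCAGATGAACCCTCGGTCACCCGGTACTGAAGCTCACATTTTGAATCGTCTGGATCTAGGATACAAAGTATCTATACTAGCGTAGATGGTTGAACTCGCTGGCCAACCTTAAATTGTTCACCCGCGGTCACAGGTGTCGTGTCCCAAAAAGACTAGCCGTTTCCTTCCTTGAGAGCTCTCTACATTTGATAGACGAATGGTGAGGGATGTTTAACCTTCGCGAACCTGGGCTCACCCAACTAATTCATCTTACCTTCTGACCATTACTCGGGTATTAATCCCGCCGTCCAATCAGAAAAACTCGAGGCACGCCGCTAATTAAG",
    "11": "GTCGCGGATTCACCGACTTGGTAGATCATATGCCCCATATTTATGGTTGCGAGTAATCTCAGCGCCGTCCGCGAATCACGTGTCGCATTTGAGCCTATAAGAATTGGTATCATTCTAAGCGATGTATCAGACGTCCCACTGGATTTGTCACATGGGGGACGAGAGTAGGGGAGGACCTTAGGCTAAGTATTGGGGCTAGCGCCGAAAGACGCGGACACGCTAGGGGCTACCGTATCGGCAGGCGTAGAAAGCCCAGAGTTGAGTCGCGTTCTAGATGATCCTATGCCAACCAAGCTTTCAGAGGGGTCCAAGTGGCTGGATGTCTTCCGATAAATGCTCCGCTGTGCGAGCGTCCACTTTGCGGCTACGGTGTGAACTCTCGTGCGAGTGTGGTTGCGAG",
    "12": "GTGCTGATTCGTGTGGCATGGAGACATGTTACGGAGAGGCGGAGCACAATGGTTAGTGCTAGGATCTTACGTCTTAAGGTGGTCGTTGACGCTCACTAACACTTCAATGGGCGTAACGTGGCTTATTGCGGAAGTCGCCCATGTCGTGAATAGTAGGTAACGAGGTAAATGAGGGATATCGAGCGGAGGGGAGGACCACTCGACTTCGCAAGTACCGCCGATACAATCGCGAGAACGTTAGAGAAACGCCTCGCAATGTGCGAGAGGCTGCGTGATGTGATGATGCTCACGTCCGATCAGTTATGCGTGCGAGGCCCTATAAGGAACGGATGGAAAGATACGGGTAGATGAACAGTTTCCAGCTGCCGAACTAGGGGGGCGTAATTATACGAAATATTAG",
    "13": "GTGCTGCAATAGAGACATGCGATCTCGGGACTAGCACTGCGTTCCTGGTATTGGAAGGGGCAGATGATTTGTCTAAGGGCGGAAGAATCGTTCATCAACATAGCCGCATCTCAACGGTGGGTGTGACTACCCGCGCGGGCTAAGATACGTCGTTCATGGTTATTTGTAATTAGTCATCAGAATACAATTTGCCCCACAGGAGGGATCCATTTGACCAATTCTTGTTGGAGGTTACTACGATTGATATTGCCGGAAACCGATGAATACTTATGCAGTCACTTCGATGTATTCACTTGTTTCATTGGTTTCCGGAAGTTTCCCGGTGACGGCTGTCACCGCCAACGTCATGTCGGTTCTCTGGCACCCCTCATGCATTCGCAGCTCCAATGAGCCATGTGAG"
  }
}
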