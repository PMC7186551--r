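# CLN2 smFISH probe set, Quasar 570, one sequence per line
ttgatgacgagtcccatacg
cggatagtagtccggtttag
attctgcattagatagctca
ttcttgcagcatttcgaagt
aacattggtggagatttctt
gctggtctattagttttgga
taatgttggaccttgtttcc
ccacagacagctcgaacaaa
ataccatttgtcactcgagt
ctcttggaacaatagcggtc
acaaccaatttggcttggtc
agccaaccagagacaagtag
atgatgtgattacaaccgcc
ccagtagggatgactacatt
gggttgggaccataaaatct
cagagagtcgaggtatacgt
gaccatcaccacagtaatga
gtctagtatatgtctttcca
gactgacgtttttcagagca
tctacagtggcatcactatc
tttaagtcttcttcttcttc
ctaagtaagtcgtactgcca
gagaatatgccgtgcgatac
aaaggaccgtggtcttgatt
gctttctgatgtcattggag
atgccgttcattaaggtact
cttccatcaaggagttagga
agaacaccattgaccgtttt
caagtgatattctttcact
gttggatgcaatttgcagtt
gatatggtaagctttctcga
ttcgaaagagcatgatgggg
gcgaaggaatggatgtgcta
gagtgtggctttgagatgag
atcagagagtgagctcatgt
catattccggctgaaaacgc
cttggagtgattggtgatga
ctgctgaccaaattggtaca
gtgctaccacatatactgtt
ttcaccagactattcacact
tttgttcgtagatcctttgt
atcattggttgcgttattgc
ttggttttccttgttagact
attgaggtaatgcgccgttg
ggggaacattccatggttaa
ctatttatggtcccagttgg
gatgaggcactgctagattt
ggtattgcccataccaaaag
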