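# Synthetic curated gene list for pipeline demonstrations and tests.
# Symbols follow the synthetic cohort generator's GENE#### vocabulary;
# this is a stand-in fixture, not a curated cancer-pathway list.
GENE0001
GENE0002
GENE0003
GENE0004
GENE0005
GENE0010
GENE0015
GENE0020
GENE0025
GENE0030
GENE0040
GENE0050
GENE0060
GENE0070
GENE0080
GENE0090
GENE0100
GENE0120
GENE0140
GENE0160
GENE0180
GENE0200
GENE0220
GENE0240
GENE0260
GENE0280
GENE0300
GENE0320
GENE0340
GENE0360
GENE0380
GENE0400
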