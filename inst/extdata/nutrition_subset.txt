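# nutrition-only subset of the bundled toy lexicon
NUTR:0001
NUTR:0002
NUTR:0003
NUTR:0004
NUTR:0005
NUTR:0006
NUTR:0007
NUTR:0008
NUTR:0009
NUTR:0010
NUTR:0011
NUTR:0012
NUTR:0013
NUTR:0014
NUTR:0015
NUTR:0016
NUTR:0017
NUTR:0018
NUTR:0019
NUTR:0020
NUTR:0021
NUTR:0022
NUTR:0023
NUTR:0024
NUTR:0025
NUTR:0026
NUTR:0027
NUTR:0028
NUTR:0029
NUTR:0030
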