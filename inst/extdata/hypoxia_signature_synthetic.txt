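# Synthetic stand-in for a hypoxia metagene signature (median-split +/-1
# scoring). Replace with the full published signature gene list for
# production use.
VEGFA
SLC2A1
PGAM1
ENO1
LDHA
TPI1
P4HA1
ADM
NDRG1
ALDOA
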