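# Synthetic stand-in for a curated spare list: taxa with strong literature
# precedence as human commensals or tumor-associated organisms; sparing
# overrides denial. Edit or replace for production use.
Fusobacterium nucleatum
Bacteroides fragilis
Helicobacter pylori
Alistipes finegoldii
Bifidobacterium bifidum
Escherichia coli
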