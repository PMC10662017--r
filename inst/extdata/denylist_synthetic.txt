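# Synthetic stand-in for a curated deny list of common reagent and
# laboratory contaminants (one taxon name per line; '#' = comment).
# Edit or replace with a full curated list for production use.
Ralstonia pickettii
Burkholderia cepacia
Bradyrhizobium japonicum
Methylobacterium radiotolerans
Sphingomonas paucimobilis
Delftia acidovorans
Acinetobacter calcoaceticus
Pseudomonas fluorescens
Cutibacterium acnes
Escherichia coli
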