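 90.00	9000	0	R	1	root
 85.00	8500	0	D	2759	  Eukaryota
 85.00	8500	8500	S	9606	    Homo sapiens
  5.00	500	0	D	2	  Bacteria
  3.00	300	0	G	561	    Escherichia
  2.50	250	250	S	562	      Escherichia coli
  0.50	50	50	S	564	      Escherichia fergusonii
  2.00	200	0	G	848	    Fusobacterium
  2.00	200	200	S	851	      Fusobacterium nucleatum
 10.00	1000	1000	U	0	unclassified
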