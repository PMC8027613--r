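genus
Ralstonia
Burkholderia
Pseudomonas
Propionibacterium
Cutibacterium
Corynebacterium
Sphingomonas
Methylobacterium
Bradyrhizobium
Mesorhizobium
Phyllobacterium
Herbaspirillum
Acinetobacter
Stenotrophomonas
Escherichia
Delftia
Comamonas
Aquabacterium
Variovorax
Staphylococcus
Streptococcus
Micrococcus
Deinococcus
Janthinobacterium
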