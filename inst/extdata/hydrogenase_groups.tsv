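group_label	ko_ids	gene_symbols
FeFe-A	K00532	hydAB
FeFe-A3	K18333	hndD
FeFe-B	K00533	hydA
FeFe-C		hydS
NiFe-1	K06281	hyaB
NiFe-2	K00437	hybC
NiFe-3a	K00440	frhA
NiFe-3b	K18016	hyhL
NiFe-3d	K00436	hoxH
NiFe-4	K14090	echE
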