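marker_name	ko_ids	gene_symbols	category	display_order
mcrA	K00399	mcrA	C1	1
pmoA	K10944	pmoA	C1	2
mxaF	K14028	mxaF	C1	3
fdhA	K05299	fdhA	C1	4
cooS/cdhA	K00198,K00192	cooS,cdhA	C1	5
acsB/cdhC	K14138,K00193	acsB,cdhC	C1	6
fdoG/fdhF	K00123,K22015	fdoG,fdhF	C1	7
coxL	K03520	coxL	C1	8
rbcL	K01601	rbcL	carbon_fixation	9
sqr	K17218	sqr	sulfur	10
soxY	K17226	soxY	sulfur	11
aprA	K00394	aprA	sulfur	12
dsrA	K11180	dsrA	sulfur	13
napA	K02567	napA	nitrogen	14
nrfA	K03385	nrfA	nitrogen	15
narG	K00370	narG	nitrogen	16
amoA	K10944	amoA	nitrogen	17
hao	K10535	hao	nitrogen	18
nirK	K00368	nirK	nitrogen	19
ccoN	K00404	ccoN	oxygen	20
coxC	K02276	coxC	oxygen	21
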