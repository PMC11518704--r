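symbol	monoisotopic_mass
H	1.00782503207
C	12.0
N	14.0030740048
O	15.9949146196
S	31.9720710015
P	30.9737616320
F	18.9984031627
Cl	34.9688526820
Br	78.9183376000
I	126.9044719000
Na	22.9897692820
K	38.9637064864
Li	7.0160034370
Si	27.9769265347
B	11.0093053645
Se	79.9165218000
Mg	23.9850416970
Ca	39.9625908630
Fe	55.9349350000
Zn	63.9291420000
Cu	62.9295977000
Mn	54.9380439000
Al	26.9815385300
As	74.9215950000
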