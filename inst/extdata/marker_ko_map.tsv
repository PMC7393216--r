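marker	ko
prk	K00855
rbcL	K01601
rbcS	K01602
sqr	K17218
fccB	K17229
dsrA	K11180
dsrB	K11181
dsrD	K11186
dsrE	K07235
dsrF	K07236
dsrH	K07237
soeA	K21307
soeB	K21308
soeC	K21309
soxB	K17224
soxY	K17226
soxZ	K17227
psrA_phsA	K08352
ttrA	K08357
ttrB	K08358
ttrC	K08359
nifH	K02588
nifD	K02586
nifK	K02591
cooS	K00198
acsB	K14138
cdhD	K00194
cdhE	K00197
doxD	K16936
doxA	K16937
amy	K01176
glk	K00845
pyg	K00688
pgm	K01835
gpi	K01810
pfk	K00850
fba	K01623
tpi	K01803
gap	K00134
pgk	K00927
gpm	K01834
eno	K01689
pk	K00873
mvhA	K14126
mvhD	K14128
mvhG	K14127
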