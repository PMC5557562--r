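residue	value
A	129
C	167
D	193
E	223
F	240
G	104
H	224
I	197
K	236
L	201
M	224
N	195
P	159
Q	225
R	274
S	155
T	172
V	174
W	285
Y	263
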