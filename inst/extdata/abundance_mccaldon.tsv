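# Natural amino-acid abundance (percent of residues) transcribed from
# McCaldon P, Argos P (1988) Proteins 4:99-122; renormalized on load.
residue	frequency
A	8.3
C	1.7
D	5.3
E	6.2
F	3.9
G	7.2
H	2.2
I	5.2
K	5.7
L	9.0
M	2.4
N	4.4
P	5.1
Q	4.0
R	5.7
S	6.9
T	5.8
V	6.6
W	1.3
Y	3.2
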