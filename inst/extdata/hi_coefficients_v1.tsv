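residue	rc	rc_nt
W	11.0	-4.0
F	10.5	-7.0
L	9.6	-9.0
I	8.4	-8.0
M	5.8	-5.5
V	5.0	-5.5
Y	4.0	-3.0
A	0.8	-1.5
T	0.4	5.0
P	0.2	4.0
E	0.0	1.0
D	-0.5	0.9
C	-0.8	4.0
S	-0.8	5.0
Q	-0.9	1.0
G	-0.9	5.0
N	-1.2	5.0
R	-1.3	8.0
H	-1.3	4.0
K	-1.9	4.6
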