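bin	family	activity
A	nirK	1.5
C	nirK	1.7
D	nirS	0.1
D	nirS	3.2
E	nirS	2.6
J	nirS	0.0
J	nirS	3.8
K	nirS	3.9
L	nirS	NA
L	nirS	NA
M	nirS	NA
A	nosZ	31
A	nosZ	7.4
A	nosZ	25
B	nosZ	1.5
D	nosZ	1.9
E	nosZ	4.9
F	nosZ	4.4
H	nosZ	0.8
I	nosZ	1.4
I	nosZ	2.7
J	nosZ	3.8
J	nosZ	3.7
K	nosZ	3.4
L	nosZ	0.6
N	nosZ	NA
F	pflB	0.04
F	pflB	1.4
F	pflB	0.1
G	pflB	NA
G	pflB	1.2
G	pflB	NA
H	pflB	1.8
H	pflB	NA
H	pflB	NA
O	pflB	NA
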