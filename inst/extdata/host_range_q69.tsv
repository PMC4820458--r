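strain	origin	susceptible
CECT481T	type_strain	+
15a	dairy	-
18a	dairy	+
19a	dairy	+
23a	dairy	+
28a	dairy	-
52c	dairy	+
54c	dairy	-
57c	dairy	+
63c	dairy	+
CECT4039	dairy	-
BA62	dairy	-
BA64	dairy	-
V61	dairy	-
V63	dairy	-
LMG20645	meat	-
LMG12161	meat	-
CECT795	human	+
CECT4176	human	-
HFS25	human	-
HFS57	human	+
HFS59	human	+
HFS62	human	-
HFS66	human	-
HFS69	human	-
JH2-2	clinical	-
V583	clinical	-
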