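base	e1	e2	e3
A	0.417	-0.514	0.228
U	-0.506	0.408	-0.471
G	-0.49	0.414	0.413
C	0.379	-0.558	-0.476
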