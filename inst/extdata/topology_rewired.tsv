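# Literature-derived MAPK topology, rewired variant: JNK is regulated
# independently of Akt (promoted to an input node, in-degree 0).
Akt	IKK
JNK	c-Jun
JNK	P53
JNK	ATF-2
P38	P53
P38	ATF-2
P38	CREB
MEK1	ERK1/2
ERK1/2	CREB
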