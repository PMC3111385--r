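id	subfamily	species_tag	h2	h5	le1	le2	npa1	npa2	substrate
CrMIPD1;1	MIPD	Cr	N	A	A	R	NPA	NPA	glycerol
CrMIPD2;1	MIPD	Cr	T	L	S	R	NPL	NPA	water/glycerol
VcMIPD1;1	MIPD	Vc	N	A	A	R	NPA	NPA	glycerol
VcMIPD2;1	MIPD	Vc	T	L	S	R	NPA	NPA	water/glycerol
VcMIPD4;1	MIPD	Vc	N	A	T	H	NPT	NPA	glycerol
CcMIPD1;1	MIPD	Cc	N	A	A	R	NPA	NPA	glycerol
CcMIPD3;1	MIPD	Cc	S	T	A	R	NPA	NPA	water/glycerol
CnMIPD1;1	MIPD	Cn	N	A	A	R	NPA	NPA	glycerol
CcMIPA1;1	MIPA	Cc	H	M	M	R	NPM	NPA	water
CcPIP4;1	PIP	Cc	F	H	C	R	NPA	NPA	water
CcPIP4;2	PIP	Cc	F	H	C	R	NPA	NPA	water
CcGIP1;1	GIP	Cc	F	L	N	R	NPA	NPA	glycerol
CnGIP1;1	GIP	Cn	F	I	I	R	NPA	NPA	glycerol
CnMIPE1;1	MIPE	Cn	F	H	C	R	NPA	NPA	water
CnMIPE1;2	MIPE	Cn	A	H	C	R	NAA	NPT	water
CnMIPE1;3	MIPE	Cn	F	H	C	R	NPA	NPA	water
OrMIPE1;1	MIPE	Or	F	H	C	R	NPA	NPA	water
MpMIPC1;1	MIPC	Mp	L	C	G	V	NPT	NPA	unknown
MrMIPC1;1	MIPC	Mr	I	T	G	V	NPT	NPA	unknown
OtMIPC1;1	MIPC	Ot	V	M	C	P	NPV	NPS	unknown
OlMIPB1;1	MIPB	Ol	Y	L	G	R	NPS	NAA	water
OrMIPB1;1	MIPB	Or	Y	F	G	R	NPS	NAA	water
PbcvMT325GIP1;1	GIP	PbcvMT325	F	V	I	R	NPA	NPA	glycerol
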