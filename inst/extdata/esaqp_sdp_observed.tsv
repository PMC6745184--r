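name	substrate	SDP1	SDP2	SDP3	SDP4	SDP5	SDP6	SDP7	SDP8	SDP9	novel_sdp	novel_residue
EsTIP2;1	ammonia	T	L	T	V	A	S	H	P	A	NA	NA
EsTIP3;1	ammonia	T	L	G	T	A	S	H	P	A	3	G
EsNIP1;2	ammonia	F	K	F	T	G	D	L	E	T	5	G
EsNIP4;1	ammonia	F	T	F	T	A	D	L	E	T	2	T
EsNIP4;3	ammonia	F	T	F	T	A	D	L	E	T	2	T
EsPIP1;1	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsPIP1;2	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsPIP1;3	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsPIP1;4	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsPIP1;5	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsPIP2;5	boric_acid	T	I	H	P	E	L	L	T	P	NA	NA
EsNIP5;1	boric_acid	T	I	H	P	E	L	L	A	P	NA	NA
EsNIP6;1	boric_acid	T	I	H	P	E	L	L	A	P	NA	NA
EsNIP7;1	boric_acid	V	I	H	P	E	L	L	T	P	NA	NA
EsPIP1;1	co2	L	I	C	A	I	D	W	D	W	NA	NA
EsPIP1;2	co2	V	I	C	A	I	D	W	D	W	NA	NA
EsPIP1;3	co2	V	M	C	A	I	D	W	D	W	2	M
EsPIP1;4	co2	V	M	C	A	I	D	W	D	W	2	M
EsPIP1;5	co2	V	I	C	A	I	D	W	D	W	NA	NA
EsPIP2;4	co2	V	I	C	A	V	E	W	D	W	6	E
EsPIP1;1	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP1;2	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP1;3	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP1;4	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP1;5	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP2;1	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP2;2	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP2;3	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP2;4	h2o2	A	G	V	F	I	Q	F	V	P	NA	NA
EsPIP2;5	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsPIP2;6	h2o2	A	G	V	F	I	Q	F	V	P	NA	NA
EsPIP2;7	h2o2	A	G	V	F	I	H	F	V	P	NA	NA
EsTIP1;1	h2o2	S	A	L	A	I	H	Y	A	P	NA	NA
EsTIP1;2	h2o2	S	A	L	A	I	H	Y	A	P	NA	NA
EsTIP1;3	h2o2	A	A	L	S	I	H	Y	V	P	NA	NA
EsTIP2;1	h2o2	S	A	L	V	I	H	Y	V	P	NA	NA
EsTIP2;2	h2o2	S	A	L	V	I	I	Y	V	P	NA	NA
EsTIP2;3	h2o2	S	A	L	V	I	I	Y	V	P	NA	NA
EsTIP3;2	h2o2	A	A	L	A	I	H	Y	V	P	NA	NA
EsTIP4;1	h2o2	S	A	L	L	T	H	Y	V	P	NA	NA
EsNIP1;2	h2o2	S	A	L	L	V	I	Y	V	P	NA	NA
EsNIP3;1	h2o2	S	A	L	V	I	L	Y	V	P	NA	NA
EsNIP5;1	h2o2	S	A	L	V	V	L	Y	V	P	NA	NA
EsPIP1;1	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP1;2	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP1;3	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP1;4	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP1;5	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;1	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;2	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;3	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;4	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;5	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;6	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsPIP2;7	urea	H	P	F	F	L	P	G	G	N	NA	NA
EsTIP1;1	urea	H	P	F	F	L	A	G	S	N	NA	NA
EsTIP1;2	urea	H	P	F	F	L	A	G	S	N	NA	NA
EsTIP1;3	urea	H	P	F	F	L	A	G	S	N	NA	NA
EsTIP2;1	urea	H	P	F	A	L	P	G	S	N	NA	NA
EsTIP2;2	urea	H	P	L	A	L	P	G	S	N	NA	NA
EsTIP2;3	urea	H	P	L	A	L	P	G	S	N	NA	NA
EsTIP2;4	urea	H	P	F	V	L	P	G	S	N	NA	NA
EsTIP3;1	urea	H	P	F	L	L	P	G	S	N	NA	NA
EsTIP3;2	urea	H	P	L	L	L	P	G	S	N	NA	NA
EsTIP4;1	urea	H	P	I	L	L	A	G	S	N	NA	NA
EsTIP5;1	urea	H	P	F	A	L	P	G	S	N	NA	NA
EsNIP1;2	urea	H	P	I	A	L	P	G	S	N	NA	NA
EsNIP2;1	urea	H	P	I	A	L	E	G	S	N	NA	NA
EsNIP3;1	urea	H	P	I	A	L	P	G	S	N	NA	NA
EsNIP4;1	urea	H	P	V	A	L	P	G	S	N	NA	NA
EsNIP4;2	urea	H	P	F	A	L	P	G	S	N	NA	NA
EsNIP4;3	urea	H	P	I	A	L	P	G	S	N	NA	NA
EsNIP5;1	urea	H	P	I	A	L	P	G	S	N	NA	NA
EsNIP6;1	urea	H	P	I	A	L	P	S	S	N	NA	NA
EsNIP7;1	urea	H	P	I	A	V	P	G	S	N	NA	NA
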