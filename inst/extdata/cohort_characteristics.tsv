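characteristic	category	count
gender	male	27
gender	female	4
age	ge60	20
age	lt60	11
smoking	yes	25
smoking	no	6
histology	SqCC	26
histology	ADC	4
histology	LCA	1
stage	IA	10
stage	IB	4
stage	IIA	1
stage	IIB	5
stage	IIIA	5
stage	IIIB	3
stage	IVA	1
stage	unstaged	2
response	responder	12
response	non_responder	17
response	not_evaluated	2
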