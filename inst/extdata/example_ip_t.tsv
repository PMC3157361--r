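# interaction_potential variant=IP_T max_before_norm=3.73
receptor_aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.0911528150134048	-0.0455764075067024	-0.0482573726541555	-0.0884718498659517	-0.0241286863270778	-0.0348525469168901	-0.096514745308311	1	-0.0160857908847185	-0.0375335120643432	-0.0616621983914209	-0.0831099195710456	-0.0187667560321716	-0.0348525469168901	-0.0697050938337802	-0.0536193029490617	-0.0750670241286863	-0.0134048257372654	-0.0482573726541555	-0.0589812332439678
R	-0.00268096514745308	0	-0.00536193029490617	-0.00268096514745308	0	0.00536193029490617	-0.00268096514745308	0	0.00268096514745308	0.00268096514745308	0.00536193029490617	0	0	-0.00268096514745308	-0.00268096514745308	-0.00536193029490617	0.00536193029490617	-0.00268096514745308	0.00268096514745308	0.00268096514745308
N	-0.00536193029490617	-0.00268096514745308	0.00536193029490617	0	-0.00268096514745308	0.00268096514745308	-0.00268096514745308	0.00536193029490617	0	0	0.00536193029490617	0	0	0	-0.00268096514745308	0.00268096514745308	0	0.00268096514745308	0	-0.00804289544235925
D	-0.00268096514745308	0	0	0.00268096514745308	0.00536193029490617	0.00268096514745308	0.00268096514745308	0	0	0	0	0	0	0	0	-0.00536193029490617	-0.00804289544235925	0	0	0.00268096514745308
C	0.00536193029490617	0	-0.00268096514745308	-0.00804289544235925	-0.00268096514745308	0	0.00268096514745308	0.00268096514745308	0	0	0	-0.00268096514745308	0.00268096514745308	0	-0.00268096514745308	0.00268096514745308	0.00268096514745308	0	0	0
Q	0	0.00268096514745308	0	0	0	0.00268096514745308	-0.00268096514745308	-0.00268096514745308	-0.00268096514745308	0	0	0.00268096514745308	0	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	0	0	0	0.00536193029490617
E	0.00536193029490617	0	0	0.00268096514745308	0	0.00536193029490617	0.00536193029490617	0.00268096514745308	-0.00268096514745308	-0.00536193029490617	-0.0107238605898123	0.00536193029490617	-0.00268096514745308	0.00536193029490617	0	-0.00268096514745308	-0.0107238605898123	0	0.00268096514745308	0
G	0.00268096514745308	0.00268096514745308	-0.00536193029490617	0	0	0	0	-0.00536193029490617	-0.00536193029490617	0	0.00536193029490617	-0.00536193029490617	0	0.00804289544235925	0.00268096514745308	0	0.00268096514745308	-0.00268096514745308	-0.00268096514745308	0.00268096514745308
H	0.0107238605898123	0	0.00804289544235925	0.00804289544235925	0	0	-0.00804289544235925	0	0	0	0	-0.0107238605898123	-0.00268096514745308	-0.0107238605898123	0.00268096514745308	0.00268096514745308	0.00268096514745308	0	0	-0.00268096514745308
I	0.0107238605898123	-0.00536193029490617	-0.00536193029490617	-0.00536193029490617	-0.00268096514745308	0.00536193029490617	0.00804289544235925	-0.00536193029490617	-0.00268096514745308	-0.00268096514745308	-0.00536193029490617	0.0134048257372654	0	0	0	-0.00536193029490617	-0.00268096514745308	0.00268096514745308	0.00536193029490617	-0.00268096514745308
L	-0.00268096514745308	0.00268096514745308	0	0	0.00268096514745308	0	-0.00268096514745308	0	0	0	-0.00268096514745308	0	0.00268096514745308	0	0	0	0.00268096514745308	0	0	-0.00268096514745308
K	0.00536193029490617	0	-0.00268096514745308	0	0	0.00268096514745308	0.00536193029490617	-0.00536193029490617	0.00268096514745308	0	0	-0.00536193029490617	0	0	0	-0.00536193029490617	0	0	0	0.00268096514745308
M	0.0134048257372654	-0.00268096514745308	-0.0107238605898123	0.00268096514745308	0	-0.00804289544235925	0.00268096514745308	-0.00268096514745308	0.00268096514745308	0	0.0107238605898123	0.00268096514745308	0	0	-0.00536193029490617	-0.00268096514745308	-0.00536193029490617	0	0	0.00268096514745308
F	-0.00536193029490617	0.00804289544235925	0	0.00268096514745308	0	-0.00268096514745308	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	-0.00268096514745308	0	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	-0.00536193029490617	0.00268096514745308	0.00536193029490617	0	0.00536193029490617	0.00268096514745308
P	0.00268096514745308	-0.00268096514745308	0.00268096514745308	0	0	0	0	0	0	0.00268096514745308	0.00268096514745308	0.00536193029490617	0	-0.00268096514745308	0	0	-0.00268096514745308	0	-0.00268096514745308	-0.00536193029490617
S	0	0.00268096514745308	0.00804289544235925	-0.00536193029490617	0	0.00268096514745308	0.0107238605898123	-0.00536193029490617	0	-0.00536193029490617	0	0	0	0.00268096514745308	0	-0.00268096514745308	-0.00804289544235925	-0.00268096514745308	0.00268096514745308	0
T	-0.00268096514745308	0.00268096514745308	0	-0.00268096514745308	-0.00268096514745308	0.00536193029490617	-0.00536193029490617	-0.00804289544235925	0.00268096514745308	0.00268096514745308	0	0.00268096514745308	0.00268096514745308	-0.00268096514745308	0.00268096514745308	-0.00536193029490617	0	0.00268096514745308	0.00268096514745308	0.00268096514745308
W	-0.00268096514745308	0.00268096514745308	0.00536193029490617	0.00536193029490617	0	0.00804289544235925	0	-0.00536193029490617	0	0	-0.00268096514745308	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	-0.00268096514745308	0.00536193029490617	0	0.00268096514745308	-0.00536193029490617	-0.00536193029490617
Y	0	-0.00536193029490617	-0.00268096514745308	-0.00268096514745308	-0.00268096514745308	0	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	-0.00536193029490617	0	0.00804289544235925	-0.00268096514745308	0.00536193029490617	0.00804289544235925	0	0.00268096514745308	0	0.00268096514745308	0
V	0	-0.00536193029490617	-0.00536193029490617	0.00268096514745308	-0.00536193029490617	0.00536193029490617	-0.00536193029490617	0.00268096514745308	-0.00268096514745308	0.00536193029490617	-0.00536193029490617	0.00536193029490617	-0.00268096514745308	0.00536193029490617	0	0.00268096514745308	0.00268096514745308	-0.00268096514745308	0	0.00268096514745308
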