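# contact_matrix template_id=example_complex
receptor_pos	L1	L2	L3	L4	L5	L6
1	1	0	0	0	0	0
2	0	1	0	0	0	0
3	0	0	1	0	0	0
4	0	0	0	1	0	0
5	0	0	0	0	1	0
6	0	0	0	0	0	0
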