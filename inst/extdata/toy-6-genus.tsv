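genus	s00001	s00002	s00003	s00004	s00005	s00006	s00007	s00008	s00009	s00010	s00011	s00012
gA	1	1	1	1	0	1	1	1	0	0	0	0
gB	1	1	1	1	0	1	1	1	0	0	0	0
gC	0	1	0	1	0	1	1	1	0	0	0	1
gD	1	0	1	0	1	0	0	0	1	1	1	0
gE	0	1	1	0	0	1	1	0	1	0	1	1
gF	1	0	1	1	1	0	0	1	0	0	0	0
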