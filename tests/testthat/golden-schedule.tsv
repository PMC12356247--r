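# j_hz=50
# delta_a_s=0.001
# delta_b_s=0.003
# switch_margin_s=0.002
# t1_max_s=0.02
# n_increments=11
# base_scans=2
# rounding_mode=nearest-integer
# boost_cap=after-zero-crossing
# mode=sr
index	t1_s	delta_used	t_eff_s	phase_sign	n_scans	residual
1	0	A	0.002	1	2	1.05146222423827
2	0.002	A	0.004	1	2	1.23606797749979
3	0.004	A	0.006	1	3	1.13420107780272
4	0.006	B	0.012	-1	2	1
5	0.008	B	0.014	-1	2	1
6	0.01	B	0.016	-1	2	1
7	0.012	B	0.018	-1	2	1
8	0.014	B	0.02	-1	2	1
9	0.016	B	0.022	-1	2	1
10	0.018	B	0.024	-1	2	1
11	0.02	B	0.026	-1	2	1
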