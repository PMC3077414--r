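sample	ct_ip	ct_noab	delta_ct_printed	fold_printed
32	29.85	38.39	8.55	374.29
33	30.76	37.01	6.25	76.21
35	30.37	39.23	8.86	464.65
36	29.49	36.46	6.97	125.37
37	29.84	37.41	7.57	190.15
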