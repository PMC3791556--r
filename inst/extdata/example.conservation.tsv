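chr2	6	0.245
chr2	7	0.422
chr2	8	0.42
chr2	9	0.763
chr2	10	0.618
chr2	11	0.52
chr2	12	0.684
chr2	13	0.448
chr2	14	0.498
chr2	20	0.767
chr2	21	0.741
chr2	22	0.916
chr2	23	0.858
chr2	24	0.819
chr2	25	0.626
chr2	26	0.662
chr2	27	0.693
chr2	28	0.539
chr2	35	0.532
chr2	36	0.608
chr2	37	0.64
chr2	38	0.564
chr2	39	0.718
chr2	40	0.653
chr2	41	0.726
chr2	42	0.746
chr2	43	0.639
chr2	44	0.586
chr2	45	0.318
chr2	46	0.378
chr2	47	0.328
chr2	48	0.324
chr2	49	0.389
chr2	50	0.488
chr2	51	0.568
chr2	52	0.501
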