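# factor: SRSF1
# threshold: 1.956
# note: synthetic position weight matrix; width and threshold follow the
# published SRSF1 (SF2/ASF) ESEfinder matrix, the weights do not.
pos	A	C	G	U
1	-1.35	0.48	0.10	-2.30
2	0.52	-1.10	-0.05	-2.05
3	-2.20	0.41	-1.25	0.08
4	0.46	-0.95	0.12	-2.40
5	-1.15	0.55	-2.10	0.02
6	0.05	-2.25	0.44	-1.30
7	0.49	-1.05	0.07	-2.15
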