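# factor: SRSF2
# threshold: 2.383
# note: synthetic position weight matrix; width and threshold follow the
# published SRSF2 (SC35) ESEfinder matrix, the weights do not.
pos	A	C	G	U
1	-2.15	0.10	0.47	-1.20
2	-1.30	0.51	-2.20	0.06
3	0.08	-1.15	0.49	-2.35
4	0.53	-2.10	0.04	-1.25
5	-2.25	0.46	-1.10	0.09
6	0.11	0.50	-2.30	-1.15
7	-1.20	0.03	0.52	-2.15
8	0.48	-1.35	-2.05	0.07
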