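# factor: SRSF5
# threshold: 2.67
# note: synthetic position weight matrix; width and threshold follow the
# published SRSF5 (SRp40) ESEfinder matrix, the weights do not.
pos	A	C	G	U
1	0.62	-1.20	0.10	-2.45
2	-2.30	0.58	-1.15	0.05
3	0.60	-2.20	0.08	-1.30
4	-1.25	0.12	0.61	-2.35
5	0.07	0.59	-2.25	-1.10
6	0.63	-1.35	-2.10	0.09
7	-2.20	0.06	0.57	-1.25
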