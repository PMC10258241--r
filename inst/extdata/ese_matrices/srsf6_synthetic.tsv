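# factor: SRSF6
# threshold: 2.676
# note: synthetic position weight matrix; width and threshold follow the
# published SRSF6 (SRp55) ESEfinder matrix, the weights do not.
pos	A	C	G	U
1	-2.35	0.09	-1.20	0.66
2	0.10	-2.25	0.68	-1.15
3	-1.30	0.70	-2.30	0.05
4	0.67	-1.10	0.08	-2.40
5	-2.20	0.04	0.69	-1.25
6	0.11	0.65	-1.30	-2.30
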