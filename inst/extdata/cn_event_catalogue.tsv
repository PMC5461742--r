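# Recurrent arm-level copy-number events with approximate hg19 arm coordinates.
# Coordinates are 1-based inclusive; these are simulation/labelling conventions.
region	chrom	start	end	direction
3p	3	1	90500000	loss
4p	4	1	49600000	loss
5q	5	49400000	180915260	loss
9p	9	1	47300000	loss
11	11	1	135006516	loss
18q	18	18500000	78077248	loss
3q	3	93500000	198022430	gain
5p	5	1	46400000	gain
7	7	1	159138663	gain
8q	8	46800000	146364022	gain
12p	12	1	34800000	gain
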