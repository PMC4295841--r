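# structplast synthetic fixture: plausible distribution of the number of
# potential synapses P per connection, discretised unimodal bump with most
# mass below P = 12. SYNTHETIC stand-in emulating morphology-based
# estimates; not ground truth from any published reconstruction.
P	prob
1	0.010
2	0.020
3	0.040
4	0.065
5	0.090
6	0.110
7	0.120
8	0.120
9	0.110
10	0.095
11	0.075
12	0.055
13	0.035
14	0.022
15	0.013
16	0.008
17	0.005
18	0.003
19	0.002
20	0.002
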