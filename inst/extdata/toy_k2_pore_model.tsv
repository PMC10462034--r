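kmer	level_mean	level_stdv
AA	60	2
AC	64	2
AG	68	2
AT	72	2
CA	76	2
CC	80	2
CG	84	2
CT	88	2
GA	92	2
GC	96	2
GG	100	2
GT	104	2
TA	108	2
TC	112	2
TG	116	2
TT	120	2
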