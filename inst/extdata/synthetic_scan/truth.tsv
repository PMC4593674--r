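gene	selected	kappa	omega0	p0	p1	omega2	L	seed
g0001	TRUE	1.59167837596033	0.112357271218207	0.659080690075643	0.250991883219685	8	328	1021176644
g0002	TRUE	2.75873978377786	0.20893311877735	0.650703422571532	0.262282095770352	8	308	1604046113
g0003	FALSE	1.94791982753668	0.274979982548393	0.662171334354207	0.272270413993392	1	295	104734866
g0004	FALSE	1.54714863491245	0.0846820237115025	0.643503274819814	0.276490563156549	1	327	1081688513
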