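system	nin	confidence	k	dmu0	dh0	ds0	h0p_rel	s0p	cp0p
n-butane	3	95	7	5.4	-0.65	-30.3	9.9	302.1	64.5
n-butane	3	99.9	20	4.1	-0.51	-23.1	9.7	295.4	64.5
BmimNTf2	23	95	7	10.1	-0.9	-55.1	33.4	669.7	257.8
BmimNTf2	23	99.9	8	9.1	-0.53	-48.0	33.0	662.7	257.8
BmimPF6	18	95	6	13.4	-1.2	-73.1	26.2	591.1	200.2
BmimPF6	18	99.9	8	10.9	-2.3	-66.1	27.3	584.1	200.2
n-butanol	4	95	4	8.2	-1.0	-46.5	11.0	334.3	70.7
n-butanol	4	99.9	8	6.0	-1.1	-35.0	11.1	322.8	70.7
octadecane	17	95	4	12.6	-6.2	-93.7	33.8	654.7	233.1
n-octane	7	95	7	7.1	-0.4	-37.4	14.7	393.7	104.8
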