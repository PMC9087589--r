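child	mother	father	sex	context	category
0	0	0	unknown	autosomal	none
0	0	1	unknown	autosomal	none
0	0	2	unknown	autosomal	none
0	1	0	unknown	autosomal	none
0	1	1	unknown	autosomal	none
0	1	2	unknown	autosomal	none
0	2	0	unknown	autosomal	none
0	2	1	unknown	autosomal	none
0	2	2	unknown	autosomal	none
1	0	0	unknown	autosomal	hetero_gain
1	0	1	unknown	autosomal	none
1	0	2	unknown	autosomal	none
1	1	0	unknown	autosomal	none
1	1	1	unknown	autosomal	none
1	1	2	unknown	autosomal	none
1	2	0	unknown	autosomal	none
1	2	1	unknown	autosomal	none
1	2	2	unknown	autosomal	none
2	0	0	unknown	autosomal	homo_gain
2	0	1	unknown	autosomal	homo_gain
2	0	2	unknown	autosomal	homo_gain
2	1	0	unknown	autosomal	homo_gain
2	1	1	unknown	autosomal	homo_inherit
2	1	2	unknown	autosomal	none
2	2	0	unknown	autosomal	homo_gain
2	2	1	unknown	autosomal	none
2	2	2	unknown	autosomal	none
0	0	0	male	x_nonpar	none
0	1	0	male	x_nonpar	none
0	2	0	male	x_nonpar	none
1	0	0	male	x_nonpar	homo_gain
1	1	0	male	x_nonpar	homo_inherit
1	2	0	male	x_nonpar	homo_inherit
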