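id,label,hemisphere
1,bankssts,left
2,caudal anterior cingulate,left
3,caudal middle frontal,left
4,cuneus,left
5,entorhinal,left
6,frontal pole,left
7,fusiform,left
8,inferior parietal,left
9,inferior temporal,left
10,insula,left
11,isthmus cingulate,left
12,lateral occipital,left
13,lateral orbitofrontal,left
14,lingual,left
15,medial orbitofrontal,left
16,middle temporal,left
17,paracentral,left
18,parahippocampal,left
19,pars opercularis,left
20,pars orbitalis,left
21,pars triangularis,left
22,pericalcarine,left
23,postcentral,left
24,posterior cingulate,left
25,precentral,left
26,precuneus,left
27,rostral anterior cingulate,left
28,rostral middle frontal,left
29,superior frontal,left
30,superior parietal,left
31,superior temporal,left
32,supramarginal,left
33,temporal pole,left
34,transverse temporal,left
35,thalamus,left
36,caudate,left
37,putamen,left
38,pallidum,left
39,hippocampus,left
40,amygdala,left
41,accumbens,left
42,bankssts,right
43,caudal anterior cingulate,right
44,caudal middle frontal,right
45,cuneus,right
46,entorhinal,right
47,frontal pole,right
48,fusiform,right
49,inferior parietal,right
50,inferior temporal,right
51,insula,right
52,isthmus cingulate,right
53,lateral occipital,right
54,lateral orbitofrontal,right
55,lingual,right
56,medial orbitofrontal,right
57,middle temporal,right
58,paracentral,right
59,parahippocampal,right
60,pars opercularis,right
61,pars orbitalis,right
62,pars triangularis,right
63,pericalcarine,right
64,postcentral,right
65,posterior cingulate,right
66,precentral,right
67,precuneus,right
68,rostral anterior cingulate,right
69,rostral middle frontal,right
70,superior frontal,right
71,superior parietal,right
72,superior temporal,right
73,supramarginal,right
74,temporal pole,right
75,transverse temporal,right
76,thalamus,right
77,caudate,right
78,putamen,right
79,pallidum,right
80,hippocampus,right
81,amygdala,right
82,accumbens,right
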