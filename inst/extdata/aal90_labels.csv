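"label","code","name","laterality"
1,"PreCG.L","left precentral gyrus","left"
2,"PreCG.R","right precentral gyrus","right"
3,"SFGdor.L","left superior frontal gyrus (dorsolateral)","left"
4,"SFGdor.R","right superior frontal gyrus (dorsolateral)","right"
5,"ORBsup.L","left superior frontal gyrus (orbital part)","left"
6,"ORBsup.R","right superior frontal gyrus (orbital part)","right"
7,"MFG.L","left middle frontal gyrus","left"
8,"MFG.R","right middle frontal gyrus","right"
9,"ORBmid.L","left middle frontal gyrus (orbital part)","left"
10,"ORBmid.R","right middle frontal gyrus (orbital part)","right"
11,"IFGoperc.L","left inferior frontal gyrus (opercular part)","left"
12,"IFGoperc.R","right inferior frontal gyrus (opercular part)","right"
13,"IFGtriang.L","left inferior frontal gyrus (triangular part)","left"
14,"IFGtriang.R","right inferior frontal gyrus (triangular part)","right"
15,"ORBinf.L","left inferior frontal gyrus (orbital part)","left"
16,"ORBinf.R","right inferior frontal gyrus (orbital part)","right"
17,"ROL.L","left rolandic operculum","left"
18,"ROL.R","right rolandic operculum","right"
19,"SMA.L","left supplementary motor area","left"
20,"SMA.R","right supplementary motor area","right"
21,"OLF.L","left olfactory cortex","left"
22,"OLF.R","right olfactory cortex","right"
23,"SFGmed.L","left superior frontal gyrus (medial)","left"
24,"SFGmed.R","right superior frontal gyrus (medial)","right"
25,"ORBsupmed.L","left superior frontal gyrus (medial orbital)","left"
26,"ORBsupmed.R","right superior frontal gyrus (medial orbital)","right"
27,"REC.L","left gyrus rectus","left"
28,"REC.R","right gyrus rectus","right"
29,"INS.L","left insula","left"
30,"INS.R","right insula","right"
31,"ACG.L","left anterior cingulate and paracingulate gyri","left"
32,"ACG.R","right anterior cingulate and paracingulate gyri","right"
33,"DCG.L","left median cingulate and paracingulate gyri","left"
34,"DCG.R","right median cingulate and paracingulate gyri","right"
35,"PCG.L","left posterior cingulate gyrus","left"
36,"PCG.R","right posterior cingulate gyrus","right"
37,"HIP.L","left hippocampus","left"
38,"HIP.R","right hippocampus","right"
39,"PHG.L","left parahippocampal gyrus","left"
40,"PHG.R","right parahippocampal gyrus","right"
41,"AMYG.L","left amygdala","left"
42,"AMYG.R","right amygdala","right"
43,"CAL.L","left calcarine fissure and surrounding cortex","left"
44,"CAL.R","right calcarine fissure and surrounding cortex","right"
45,"CUN.L","left cuneus","left"
46,"CUN.R","right cuneus","right"
47,"LING.L","left lingual gyrus","left"
48,"LING.R","right lingual gyrus","right"
49,"SOG.L","left superior occipital gyrus","left"
50,"SOG.R","right superior occipital gyrus","right"
51,"MOG.L","left middle occipital gyrus","left"
52,"MOG.R","right middle occipital gyrus","right"
53,"IOG.L","left inferior occipital gyrus","left"
54,"IOG.R","right inferior occipital gyrus","right"
55,"FFG.L","left fusiform gyrus","left"
56,"FFG.R","right fusiform gyrus","right"
57,"PoCG.L","left postcentral gyrus","left"
58,"PoCG.R","right postcentral gyrus","right"
59,"SPG.L","left superior parietal gyrus","left"
60,"SPG.R","right superior parietal gyrus","right"
61,"IPL.L","left inferior parietal gyrus","left"
62,"IPL.R","right inferior parietal gyrus","right"
63,"SMG.L","left supramarginal gyrus","left"
64,"SMG.R","right supramarginal gyrus","right"
65,"ANG.L","left angular gyrus","left"
66,"ANG.R","right angular gyrus","right"
67,"PCUN.L","left precuneus","left"
68,"PCUN.R","right precuneus","right"
69,"PCL.L","left paracentral lobule","left"
70,"PCL.R","right paracentral lobule","right"
71,"CAU.L","left caudate nucleus","left"
72,"CAU.R","right caudate nucleus","right"
73,"PUT.L","left lenticular nucleus putamen","left"
74,"PUT.R","right lenticular nucleus putamen","right"
75,"PAL.L","left lenticular nucleus pallidum","left"
76,"PAL.R","right lenticular nucleus pallidum","right"
77,"THA.L","left thalamus","left"
78,"THA.R","right thalamus","right"
79,"HES.L","left Heschl gyrus","left"
80,"HES.R","right Heschl gyrus","right"
81,"STG.L","left superior temporal gyrus","left"
82,"STG.R","right superior temporal gyrus","right"
83,"TPOsup.L","left temporal pole (superior temporal gyrus)","left"
84,"TPOsup.R","right temporal pole (superior temporal gyrus)","right"
85,"MTG.L","left middle temporal gyrus","left"
86,"MTG.R","right middle temporal gyrus","right"
87,"TPOmid.L","left temporal pole (middle temporal gyrus)","left"
88,"TPOmid.R","right temporal pole (middle temporal gyrus)","right"
89,"ITG.L","left inferior temporal gyrus","left"
90,"ITG.R","right inferior temporal gyrus","right"
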