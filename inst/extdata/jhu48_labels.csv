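"label","code","name","laterality"
1,"MCP","middle cerebellar peduncle","midline"
2,"PCT","pontine crossing tract","midline"
3,"GCC","genu of corpus callosum","midline"
4,"BCC","body of corpus callosum","midline"
5,"SCC","splenium of corpus callosum","midline"
6,"FX","fornix (column and body)","midline"
7,"CST.R","right corticospinal tract","right"
8,"CST.L","left corticospinal tract","left"
9,"ML.R","right medial lemniscus","right"
10,"ML.L","left medial lemniscus","left"
11,"ICP.R","right inferior cerebellar peduncle","right"
12,"ICP.L","left inferior cerebellar peduncle","left"
13,"SCP.R","right superior cerebellar peduncle","right"
14,"SCP.L","left superior cerebellar peduncle","left"
15,"CP.R","right cerebral peduncle","right"
16,"CP.L","left cerebral peduncle","left"
17,"ALIC.R","right anterior limb of internal capsule","right"
18,"ALIC.L","left anterior limb of internal capsule","left"
19,"PLIC.R","right posterior limb of internal capsule","right"
20,"PLIC.L","left posterior limb of internal capsule","left"
21,"RLIC.R","right retrolenticular part of internal capsule","right"
22,"RLIC.L","left retrolenticular part of internal capsule","left"
23,"ACR.R","right anterior corona radiata","right"
24,"ACR.L","left anterior corona radiata","left"
25,"SCR.R","right superior corona radiata","right"
26,"SCR.L","left superior corona radiata","left"
27,"PCR.R","right posterior corona radiata","right"
28,"PCR.L","left posterior corona radiata","left"
29,"PTR.R","right posterior thalamic radiation","right"
30,"PTR.L","left posterior thalamic radiation","left"
31,"SS.R","right sagittal stratum","right"
32,"SS.L","left sagittal stratum","left"
33,"EC.R","right external capsule","right"
34,"EC.L","left external capsule","left"
35,"CGC.R","right cingulum (cingulate gyrus)","right"
36,"CGC.L","left cingulum (cingulate gyrus)","left"
37,"CGH.R","right cingulum (hippocampus)","right"
38,"CGH.L","left cingulum (hippocampus)","left"
39,"FXST.R","right fornix (cres) / stria terminalis","right"
40,"FXST.L","left fornix (cres) / stria terminalis","left"
41,"SLF.R","right superior longitudinal fasciculus","right"
42,"SLF.L","left superior longitudinal fasciculus","left"
43,"SFO.R","right superior fronto-occipital fasciculus","right"
44,"SFO.L","left superior fronto-occipital fasciculus","left"
45,"UNC.R","right uncinate fasciculus","right"
46,"UNC.L","left uncinate fasciculus","left"
47,"TAP.R","right tapetum","right"
48,"TAP.L","left tapetum","left"
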