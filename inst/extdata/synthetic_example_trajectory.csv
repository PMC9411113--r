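frame,x,y,orientation
0,0.000000,0.000000,79.832787
1,-0.049663,0.216848,102.899586
2,-0.123381,0.296511,132.780333
3,-0.308564,0.347001,164.748863
4,-0.433749,0.299322,-159.149793
5,-0.552654,0.171480,-132.925690
6,-0.707174,0.071512,-147.098563
7,-0.802129,-0.018616,-136.494084
8,-0.992877,-0.143894,-146.704305
9,-1.209405,-0.249220,-154.060242
10,-1.399084,-0.317148,-160.296452
11,-1.399084,-0.317148,-160.296452
12,-1.399084,-0.317148,-160.296452
13,-1.399084,-0.317148,-160.296452
14,-1.399084,-0.317148,-160.296452
15,-1.399084,-0.317148,-160.296452
16,-1.399084,-0.317148,-160.296452
17,-1.399084,-0.317148,-160.296452
18,-1.527732,-0.343041,-168.620019
19,-1.799468,-0.254984,162.044948
20,-1.799468,-0.254984,162.044948
21,-1.799468,-0.254984,162.044948
22,-1.799468,-0.254984,162.044948
23,-1.799468,-0.254984,162.044948
24,-2.024776,-0.023164,134.183853
25,-2.181904,0.148400,132.485080
26,-2.387677,0.407809,128.422863
27,-2.530516,0.550704,134.988647
28,-2.581329,0.681788,111.188397
29,-2.581329,0.681788,111.188397
30,-2.581329,0.681788,111.188397
31,-2.581329,0.681788,111.188397
32,-2.581329,0.681788,111.188397
33,-2.581329,0.681788,111.188397
34,-2.562114,0.912597,85.240894
35,-2.569470,1.177876,91.588441
36,-2.506965,1.300483,62.987517
37,-2.384017,1.380685,33.117424
38,-2.260839,1.466041,34.719844
39,-2.128950,1.603775,46.241931
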