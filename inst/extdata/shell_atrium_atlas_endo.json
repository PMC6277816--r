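{"lines":{"rim_mv":[37,48,59,70,81,82,83,84,85,74,63,52,41,40,39,38,37],"rim_lipv":[265,305,345,347,349,351,311,271,269,267,265],"rim_ripv":[266,306,346,348,350,361,321,281,270,268,266],"rim_laa":[326,366,406,446,447,448,408,368,328,327,326],"rim_lspv":[465,559,560,561,562,573,584,583,594,593,592,471,469,467,465],"rim_rspv":[466,569,568,567,566,577,588,589,600,601,602,481,470,468,466],"b|wall_q1|wall_q4#1":[57,56,141,181,221,261,301,341,381,421,461],"b|wall_q1|wall_q4#2":[540,541,542],"b|lspv_ring|wall_q1":[461,537,538,539,540],"b|lipv_ring|wall_q4":[385,383,343,303,263,223,225,185,187,189,191,231,232,272,273,313,353,352,392,391],"b|lspv_ring|wall_q4#1":[385,425,423,463,461],"b|lspv_ring|wall_q4#2":[391,431,432,433,434,474,475,596,585,574,563,552,551,540],"b|lipv_ring|lspv_ring":[385,387,389,391],"b|wall_q2|wall_q3#1":[65,66,142,182,222,262,302,342,382,422,462],"b|wall_q2|wall_q3#2":[542,543,544],"b|rspv_ring|wall_q2":[462,547,546,545,544],"b|ripv_ring|wall_q3":[386,384,344,304,264,224,226,186,188,190,201,241,240,280,279,319,359,360,400,401],"b|rspv_ring|wall_q3#1":[386,426,424,464,462],"b|rspv_ring|wall_q3#2":[401,441,440,439,438,478,477,598,587,576,565,554,555,544],"b|ripv_ring|rspv_ring":[386,388,390,401],"b|laa_ring|wall_q1":[287,286,285,325,365,364,404,444,484,485,496,497,498],"b|wall_q1|wall_q2#1":[17,6,127,167,207,247,287],"b|wall_q1|wall_q2#2":[498,509,520,531,542],"b|laa_ring|wall_q2":[287,288,289,329,369,370,410,450,490,489,500,499,498],"b|wall_q3|wall_q4":[105,116,156,196,236,276,316,356,396,436,476,597,586,575,564,553,542],"b|mv_ring|wall_q1":[17,16,15,26,25,36,35,46,57],"b|mv_ring|wall_q4":[57,68,79,80,91,92,103,104,105],"b|mv_ring|wall_q2":[17,18,19,30,31,42,43,54,65],"b|mv_ring|wall_q3":[65,76,87,86,97,96,107,106,105]},"regions":[{"name":"mv_ring","gamma0":["rim_mv"],"gamma1":["b|mv_ring|wall_q1","b|mv_ring|wall_q4","b|mv_ring|wall_q2","b|mv_ring|wall_q3"],"orthogonal":true,"seed":779},{"name":"rspv_ring","gamma0":["rim_rspv"],"gamma1":["b|rspv_ring|wall_q2","b|rspv_ring|wall_q3#1","b|rspv_ring|wall_q3#2","b|ripv_ring|rspv_ring"],"orthogonal":true,"seed":301},{"name":"ripv_ring","gamma0":["rim_ripv"],"gamma1":["b|ripv_ring|wall_q3","b|ripv_ring|rspv_ring"],"orthogonal":true,"seed":309},{"name":"lspv_ring","gamma0":["rim_lspv"],"gamma1":["b|lspv_ring|wall_q1","b|lspv_ring|wall_q4#1","b|lspv_ring|wall_q4#2","b|lipv_ring|lspv_ring"],"orthogonal":true,"seed":119},{"name":"lipv_ring","gamma0":["rim_lipv"],"gamma1":["b|lipv_ring|wall_q4","b|lipv_ring|lspv_ring"],"orthogonal":true,"seed":127},{"name":"laa_ring","gamma0":["rim_laa"],"gamma1":["b|laa_ring|wall_q1","b|laa_ring|wall_q2"],"orthogonal":true,"seed":419},{"name":"wall_q1","gamma0":["b|wall_q1|wall_q4#1","b|wall_q1|wall_q4#2"],"gamma1":["b|wall_q1|wall_q2#1","b|wall_q1|wall_q2#2"],"orthogonal":false,"seed":1},{"name":"wall_q2","gamma0":["b|wall_q1|wall_q2#1","b|wall_q1|wall_q2#2"],"gamma1":["b|wall_q2|wall_q3#1","b|wall_q2|wall_q3#2"],"orthogonal":false,"seed":183},{"name":"wall_q3","gamma0":["b|wall_q2|wall_q3#1","b|wall_q2|wall_q3#2"],"gamma1":["b|wall_q3|wall_q4"],"orthogonal":false,"seed":283},{"name":"wall_q4","gamma0":["b|wall_q3|wall_q4"],"gamma1":["b|wall_q1|wall_q4#1","b|wall_q1|wall_q4#2"],"orthogonal":false,"seed":101}],"labels":[7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,4,4,10,10,10,10,10,10,5,5,5,5,5,5,5,5,10,10,4,4,4,4,10,10,10,10,5,5,5,5,5,5,4,4,4,4,10,10,10,10,5,5,5,5,5,5,4,4,4,4,10,10,10,10,5,5,5,5,5,5,4,4,4,4,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,2,2,9,9,9,9,9,9,3,3,3,3,3,3,3,3,9,9,2,2,2,2,9,9,9,9,3,3,3,3,3,3,2,2,2,2,9,9,9,9,3,3,3,3,3,3,2,2,2,2,9,9,9,9,3,3,3,3,3,3,2,2,2,2,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,6,6,6,6,6,6,7,7,7,7,7,7,7,7,7,7,6,6,6,6,6,6,6,6,6,6,7,7,7,7,7,7,7,7,7,7,6,6,6,6,8,8,8,8,8,8,8,8,8,8,6,6,6,6,8,8,8,8,8,8,8,8,8,8,6,6,6,6,6,6,6,6,6,6,8,8,8,8,8,8,8,8,8,8,8,8,8,8,6,6,6,6,6,6,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,8,10,10,10,10,10,10,5,5,5,5,5,5,5,5,10,10,4,4,4,4,10,10,10,10,10,10,10,10,5,5,5,5,10,10,10,10,4,4,4,4,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,4,4,4,4,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,4,4,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,2,2,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,9,2,2,2,2,9,9,9,9,9,9,9,9,3,3,3,3,9,9,9,9,2,2,2,2,9,9,9,9,9,9,3,3,3,3,3,3,3,3,9,9,2,2,2,2,7,7,7,7,7,7,7,7,7,7,10,10,10,10,10,10,10,10,10,10,7,7,7,7,7,7,1,1,1,1,1,1,1,1,10,10,10,10,10,10,7,7,7,7,1,1,1,1,1,1,1,1,1,1,1,1,10,10,10,10,7,7,1,1,1,1,1,1,1,1,10,10,7,7,1,1,1,1,1,1,1,1,10,10,8,8,1,1,1,1,1,1,1,1,9,9,8,8,1,1,1,1,1,1,1,1,9,9,8,8,8,8,1,1,1,1,1,1,1,1,1,1,1,1,9,9,9,9,8,8,8,8,8,8,1,1,1,1,1,1,1,1,9,9,9,9,9,9,8,8,8,8,8,8,8,8,8,8,9,9,9,9,9,9,9,9,9,9,7,7,7,7,7,7,7,7,7,7,4,4,4,4,7,7,7,7,7,7,7,7,7,7,4,4,4,4,7,7,7,7,7,7,7,7,7,7,4,4,4,4,4,4,6,6,7,7,7,7,7,7,7,7,10,10,4,4,4,4,4,4,4,4,6,6,7,7,7,7,7,7,7,7,10,10,10,10,10,10,10,10,10,10,6,6,8,8,8,8,8,8,8,8,9,9,9,9,9,9,9,9,9,9,6,6,8,8,8,8,8,8,8,8,9,9,2,2,2,2,2,2,2,2,8,8,8,8,8,8,8,8,8,8,2,2,2,2,2,2,8,8,8,8,8,8,8,8,8,8,2,2,2,2,8,8,8,8,8,8,8,8,8,8,2,2,2,2],"landmarks":[{"name":"mv_rim_superior","vertex":81,"x":-3.32361677216588,"y":3.32361677216588,"z":-8.3090419304147},{"name":"lipv_rim_superior","vertex":345,"x":-12.0227555949305,"y":4.80910223797219,"z":2.4045511189861},{"name":"ripv_rim_superior","vertex":346,"x":12.0227555949305,"y":4.80910223797219,"z":2.4045511189861},{"name":"laa_rim_superior","vertex":447,"x":0,"y":-9.41941183567415,"z":7.53552946853932},{"name":"lspv_rim_superior","vertex":562,"x":-3.32363144182702,"y":3.32363144182702,"z":8.30907860456756},{"name":"rspv_rim_superior","vertex":566,"x":3.32363144182702,"y":3.32363144182702,"z":8.30907860456756},{"name":"roof_center","vertex":542,"x":0,"y":0,"z":9.00531025020522},{"name":"septum_center","vertex":302,"x":14.0000218898926,"y":0,"z":0},{"name":"lateral_center","vertex":301,"x":-14.0000218898926,"y":0,"z":0},{"name":"posterior_center","vertex":316,"x":0,"y":11,"z":0}]}
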