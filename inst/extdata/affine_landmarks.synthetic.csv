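x1,y1,z1,x2,y2,z2
0,0,0,2,-1,3
50,0,0,54.5,-2,3
100,0,0,107,-3,3
0,40,0,2.7999999999999998,38.200000000000003,4.2000000000000002
50,40,0,55.299999999999997,37.200000000000003,4.2000000000000002
100,40,0,107.8,36.200000000000003,4.2000000000000002
0,80,0,3.6000000000000001,77.400000000000006,5.4000000000000004
50,80,0,56.100000000000001,76.400000000000006,5.4000000000000004
100,80,0,108.59999999999999,75.400000000000006,5.4000000000000004
0,0,30,2,-0.69999999999999996,36
50,0,30,54.5,-1.7,36
100,0,30,107,-2.7000000000000002,36
0,40,30,2.7999999999999998,38.5,37.200000000000003
50,40,30,55.299999999999997,37.5,37.200000000000003
100,40,30,107.8,36.5,37.200000000000003
0,80,30,3.6000000000000001,77.700000000000003,38.400000000000006
50,80,30,56.100000000000001,76.700000000000003,38.400000000000006
100,80,30,108.59999999999999,75.700000000000003,38.400000000000006
0,0,60,2,-0.40000000000000002,69
50,0,60,54.5,-1.3999999999999999,69
100,0,60,107,-2.3999999999999999,69
0,40,60,2.7999999999999998,38.800000000000004,70.200000000000003
50,40,60,55.299999999999997,37.800000000000004,70.200000000000003
100,40,60,107.8,36.800000000000004,70.200000000000003
0,80,60,3.6000000000000001,78,71.400000000000006
50,80,60,56.100000000000001,77,71.400000000000006
100,80,60,108.59999999999999,76,71.400000000000006
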