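[[[1,null,1,0,0,0,-1,5],[2,1,1,0,0,1,-1,5],[3,2,1,0,0,2,-1,5],[4,3,1,0,0,3,-1,5],[5,4,1,0,0,4,-1,5]],[[2,1,1,0,0,1],[5,2,0,0,0,4]],{"soma":[1]}]
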