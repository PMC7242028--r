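{"spaces":[{"name":"A","unit":"um","bbox_lo":[0,0,0],"bbox_hi":[100,80,60],"mirror_axis":"x"},{"name":"B","unit":"um","bbox_lo":[-10,-10,-10],"bbox_hi":[120,95,80],"mirror_axis":"x"}],"bridges":[{"from":"A","to":"B","type":"affine","file":"A_to_B.transform.json","invertible":true}]}
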