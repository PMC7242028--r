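{"kind":"affine","matrix":[1.05,-0.02,0,0.02,0.98,0.03,0,0.01,1.1,2,-1,3]}
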