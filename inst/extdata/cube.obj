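# OBJ written by skeletoolkit
v 0 0 0
v 1 0 0
v 0 1 0
v 1 1 0
v 0 0 1
v 1 0 1
v 0 1 1
v 1 1 1
f 1 3 2
f 1 7 3
f 2 3 4
f 3 7 4
f 1 2 5
f 7 1 5
f 2 4 6
f 7 5 6
f 5 2 6
f 4 7 8
f 7 6 8
f 6 4 8
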