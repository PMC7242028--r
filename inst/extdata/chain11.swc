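# SWC skeleton written by skeletoolkit
# unit: um
# columns: id label x y z radius parent_id
1 0 0 0 0 0.5 -1
2 0 0 0 1 0.5 1
3 0 0 0 2 0.5 2
4 0 0 0 3 0.5 3
5 0 0 0 4 0.5 4
6 0 0 0 5 0.5 5
7 0 0 0 6 0.5 6
8 0 0 0 7 0.5 7
9 0 0 0 8 0.5 8
10 0 0 0 9 0.5 9
11 0 0 0 10 0.5 10
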