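# SWC skeleton written by skeletoolkit
# unit: um
# columns: id label x y z radius parent_id
1 0 0 0 0 1 -1
2 0 0 0 1 1 1
3 0 0 1 1 1 2
4 0 1 0 1 1 2
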