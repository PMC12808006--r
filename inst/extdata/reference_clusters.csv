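cluster,n
1,24017
2,5035
3,918901
4,236381
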