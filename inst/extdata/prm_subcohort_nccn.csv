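nccn,patients
1,29
2,9
3,23
4,17
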