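predicted,present,unknown,absent
present,166,19,117
unknown,1,21,39
absent,12,28,539
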