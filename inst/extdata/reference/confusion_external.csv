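predicted,suitable,unsuitable
suitable,110,8
unsuitable,5,26
undetected,1,0
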