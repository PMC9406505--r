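predicted,suitable,unsuitable
suitable,1350,126
unsuitable,66,311
undetected,12,5
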