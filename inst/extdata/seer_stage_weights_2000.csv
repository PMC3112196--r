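stage,weight
I,16.22
II,2.91
III,32.64
IV,48.23
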