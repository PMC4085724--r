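(((1,2),5),((3,4),6));
(((1,2),6),((3,4),5));
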