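taxa: a b c d e
C a b c d a,b,c,d b 0.9
C a b c e a,b,c,e b 1.0
C a b d e a,b,d,e b 0.8
T a c d e a,e|c,d 0.7
C b c d e b,c,d,e b 1.0
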