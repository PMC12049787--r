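>synthTF
A [ 90  2  3 90  3  4 90  3 ]
C [  4 92  3  3 90  3  4  3 ]
G [  3  3 90  4  3  3  3 92 ]
T [  3  3  4  3  4 90  3  2 ]
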