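subject,muscle,slow_heel,slow_forefoot,fast_heel,fast_forefoot
S1,TA,0,0,100,100
S1,SOL,25,0,100,100
S2,TA,0,25,25,50
S2,SOL,75,75,100,100
S3,TA,0,0,100,50
S3,SOL,100,100,50,25
S4,TA,75,50,100,100
S4,SOL,50,25,100,100
S5,TA,0,0,50,75
S5,SOL,0,0,100,25
S6,TA,50,25,100,100
S6,SOL,0,0,25,0
S7,TA,0,0,100,100
S7,SOL,25,0,100,100
S8,TA,0,0,50,0
S8,SOL,0,0,100,0
S9,TA,0,0,0,0
S9,SOL,0,0,0,0
S10,TA,25,0,100,100
S10,SOL,0,0,75,50
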