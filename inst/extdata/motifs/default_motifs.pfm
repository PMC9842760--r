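>ISRE
A [ 0.971154 0.00961538 0.00961538 0.00961538 0.00961538 0.00961538 0.25 0.25 0.00961538 0.00961538 0.00961538 0.00961538 ]
C [ 0.00961538 0.00961538 0.00961538 0.00961538 0.00961538 0.971154 0.25 0.25 0.00961538 0.00961538 0.00961538 0.971154 ]
G [ 0.00961538 0.971154 0.00961538 0.00961538 0.00961538 0.00961538 0.25 0.25 0.00961538 0.00961538 0.00961538 0.00961538 ]
T [ 0.00961538 0.00961538 0.971154 0.971154 0.971154 0.00961538 0.25 0.25 0.971154 0.971154 0.971154 0.00961538 ]
>GAS
A [ 0.00961538 0.00961538 0.00961538 0.25 0.25 0.25 0.00961538 0.971154 0.971154 ]
C [ 0.00961538 0.00961538 0.971154 0.25 0.25 0.25 0.00961538 0.00961538 0.00961538 ]
G [ 0.00961538 0.00961538 0.00961538 0.25 0.25 0.25 0.971154 0.00961538 0.00961538 ]
T [ 0.971154 0.971154 0.00961538 0.25 0.25 0.25 0.00961538 0.00961538 0.00961538 ]
>NFKB
A [ 0.00961538 0.00961538 0.00961538 0.490385 0.25 0.25 0.00961538 0.00961538 0.00961538 0.00961538 ]
C [ 0.00961538 0.00961538 0.00961538 0.00961538 0.25 0.25 0.490385 0.490385 0.971154 0.971154 ]
G [ 0.971154 0.971154 0.971154 0.490385 0.25 0.25 0.00961538 0.00961538 0.00961538 0.00961538 ]
T [ 0.00961538 0.00961538 0.00961538 0.00961538 0.25 0.25 0.490385 0.490385 0.00961538 0.00961538 ]
>IRE
A [ 0.00961538 0.00961538 0.00961538 0.00961538 ]
C [ 0.00961538 0.00961538 0.00961538 0.971154 ]
G [ 0.00961538 0.00961538 0.00961538 0.00961538 ]
T [ 0.971154 0.971154 0.971154 0.00961538 ]
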