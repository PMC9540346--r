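>soxlike soxlike
A  [ 5.00 85.00 5.00 5.00 5.00 5.00 5.00 85.00 5.00 ]
C  [ 85.00 5.00 5.00 5.00 5.00 5.00 5.00 5.00 5.00 ]
G  [ 5.00 5.00 5.00 5.00 85.00 5.00 5.00 5.00 5.00 ]
T  [ 5.00 5.00 85.00 85.00 5.00 85.00 85.00 5.00 85.00 ]
>sixlike sixlike
A  [ 5.00 5.00 85.00 5.00 5.00 5.00 5.00 5.00 5.00 ]
C  [ 5.00 85.00 5.00 5.00 5.00 5.00 5.00 5.00 85.00 ]
G  [ 5.00 5.00 5.00 85.00 85.00 5.00 5.00 5.00 5.00 ]
T  [ 85.00 5.00 5.00 5.00 5.00 85.00 85.00 85.00 5.00 ]
>foxlike foxlike
A  [ 5.00 5.00 5.00 5.00 5.00 85.00 5.00 5.00 5.00 ]
C  [ 5.00 5.00 5.00 5.00 5.00 5.00 85.00 5.00 5.00 ]
G  [ 5.00 85.00 5.00 5.00 5.00 5.00 5.00 5.00 5.00 ]
T  [ 85.00 5.00 85.00 85.00 85.00 5.00 5.00 85.00 85.00 ]
>gatalike gatalike
A  [ 85.00 5.00 85.00 5.00 85.00 85.00 5.00 85.00 5.00 ]
C  [ 5.00 5.00 5.00 5.00 5.00 5.00 5.00 5.00 85.00 ]
G  [ 5.00 85.00 5.00 5.00 5.00 5.00 85.00 5.00 5.00 ]
T  [ 5.00 5.00 5.00 85.00 5.00 5.00 5.00 5.00 5.00 ]
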