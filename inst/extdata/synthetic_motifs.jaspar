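>CTCFsyn CTCFsyn
A [ 1 1 1 1 1 97 1 1 1 1 1 1 97 1 1 97 1 1 1 ]
C [ 97 97 1 97 1 1 1 1 1 1 1 97 1 1 1 1 97 1 1 ]
G [ 1 1 97 1 97 1 97 97 1 97 97 1 1 97 1 1 1 1 1 ]
T [ 1 1 1 1 1 1 1 1 97 1 1 1 1 1 97 1 1 97 97 ]
>TFsynA TFsynA
A [ 1 97 1 1 97 1 97 1 97 1 1 1 ]
C [ 1 1 1 1 1 97 1 1 1 1 97 97 ]
G [ 97 1 1 1 1 1 1 97 1 1 1 1 ]
T [ 1 1 97 97 1 1 1 1 1 97 1 1 ]
>TFsynB TFsynB
A [ 1 1 1 97 1 1 1 1 97 1 1 1 1 97 ]
C [ 1 1 1 1 97 1 1 97 1 1 97 1 1 1 ]
G [ 1 1 97 1 1 97 1 1 1 1 1 97 97 1 ]
T [ 97 97 1 1 1 1 97 1 1 97 1 1 1 1 ]
>TFsynC TFsynC
A [ 97 1 1 1 97 97 1 1 1 97 1 1 1 97 1 1 ]
C [ 1 97 1 1 1 1 1 1 1 1 97 1 97 1 1 97 ]
G [ 1 1 97 97 1 1 97 1 97 1 1 1 1 1 97 1 ]
T [ 1 1 1 1 1 1 1 97 1 1 1 97 1 1 1 1 ]
>TFsynD TFsynD
A [ 1 1 1 97 1 1 1 97 97 97 1 1 1 1 1 1 1 97 1 ]
C [ 1 1 97 1 1 1 97 1 1 1 1 1 1 1 97 97 1 1 97 ]
G [ 1 97 1 1 1 97 1 1 1 1 1 1 97 97 1 1 1 1 1 ]
T [ 97 1 1 1 97 1 1 1 1 1 97 97 1 1 1 1 97 1 1 ]
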