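mutation,domain
E28K,TPR
N65S,TPR
A79D,TPR
A79T,TPR
L123V,TPR
M141I,CC
K145Q,CC
W151C,CC
S236T,Ubox
M240T,Ubox
T246M,Ubox
D253N,Ubox
D253Y,Ubox
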