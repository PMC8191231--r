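element,mass
H,1.008
C,12.011
N,14.007
O,15.999
F,18.998
P,30.974
S,32.06
CL,35.45
BR,79.904
I,126.904
SE,78.971
B,10.81
SI,28.085
NA,22.990
K,39.098
MG,24.305
CA,40.078
ZN,65.38
CU,63.546
NI,58.693
FE,55.845
MN,54.938
CO,58.933
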