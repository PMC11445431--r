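# Average residue masses in Daltons (free amino acid minus one water),
# standard biochemical values. Summing over a sequence gives the chain mass
# up to one terminal water, which is ignored here by convention.
aa,mass
G,57.05
A,71.08
S,87.08
P,97.12
V,99.13
T,101.10
C,103.14
L,113.16
I,113.16
N,114.10
D,115.09
Q,128.13
K,128.17
E,129.12
M,131.19
H,137.14
F,147.18
R,156.19
Y,163.18
W,186.21
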