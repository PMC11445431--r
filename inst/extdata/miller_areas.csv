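# Reference maximal solvent-accessible areas per residue type (A^2),
# standard-state Gly-X-Gly values of Miller et al. (1987) J Mol Biol 196:641.
# Used as the denominator of relative solvent accessibility (RSA).
resname,aa,area
ALA,A,113
ARG,R,241
ASN,N,158
ASP,D,151
CYS,C,140
GLN,Q,189
GLU,E,183
GLY,G,85
HIS,H,194
ILE,I,182
LEU,L,180
LYS,K,211
MET,M,204
PHE,F,218
PRO,P,143
SER,S,122
THR,T,146
TRP,W,259
TYR,Y,229
VAL,V,160
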