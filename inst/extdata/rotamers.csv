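resid,chi1,chi2,chi3,chi4
SER,64,NA,NA,NA
CYS,-65,NA,NA,NA
THR,62,NA,NA,NA
VAL,175,NA,NA,NA
LEU,-65,175,NA,NA
ILE,-65,170,NA,NA
ASP,-70,-15,NA,NA
ASN,-65,-40,NA,NA
GLU,-67,180,-10,NA
GLN,-67,180,-25,NA
LYS,-67,180,180,180
ARG,-67,180,180,180
MET,-67,180,75,NA
PHE,-65,90,NA,NA
TYR,-65,90,NA,NA
HIS,-65,-70,NA,NA
TRP,-65,95,NA,NA
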