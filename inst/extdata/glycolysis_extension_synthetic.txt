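SLC2A1
ALDOA
GAPDH
PKM
HK1
PFKM
PFKP
PGAM1
PGAM4
HKDC1
ADPGK
GCKR
PFKFB1
PFKFB2
PFKFB3
PFKFB4
FBP1
FBP2
PCK1
PCK2
G6PC
PDHA1
PDHB
PDK1
DLAT
DLD
MPC1
MPC2
SLC16A1
SLC16A3
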