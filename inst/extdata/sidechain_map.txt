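# MARTINI 2.x-style side-chain coarse-graining map.
# One row per amino acid: three-letter code, bead count, then one field per
# bead of the form NAME=atom,atom,...@link where `link` is the nominal
# distance (Angstrom) from the bead's anchor (CA for SC1, the previous bead
# otherwise).  GLY and ALA carry no side-chain bead.  Edit this file, not the
# code, to correct the atom-to-bead assignment.
GLY 0 -
ALA 0 -
VAL 1 SC1=CB,CG1,CG2@2.0
LEU 1 SC1=CB,CG,CD1,CD2@2.5
ILE 1 SC1=CB,CG1,CG2,CD1@2.3
PRO 1 SC1=CB,CG,CD@1.9
MET 1 SC1=CB,CG,SD,CE@2.7
CYS 1 SC1=CB,SG@2.1
SER 1 SC1=CB,OG@1.9
THR 1 SC1=CB,OG1,CG2@1.9
ASN 1 SC1=CB,CG,OD1,ND2@2.4
GLN 1 SC1=CB,CG,CD,OE1,NE2@2.9
ASP 1 SC1=CB,CG,OD1,OD2@2.4
GLU 1 SC1=CB,CG,CD,OE1,OE2@2.9
LYS 2 SC1=CB,CG,CD@2.5 SC2=CE,NZ@2.3
ARG 2 SC1=CB,CG,CD@2.5 SC2=NE,CZ,NH1,NH2@2.5
HIS 3 SC1=CB,CG@1.9 SC2=CD2,NE2@2.2 SC3=ND1,CE1@2.2
PHE 3 SC1=CB,CG@1.9 SC2=CD1,CE1@2.3 SC3=CD2,CE2,CZ@2.4
TYR 3 SC1=CB,CG@1.9 SC2=CD1,CE1@2.3 SC3=CD2,CE2,CZ,OH@2.6
TRP 4 SC1=CB,CG@2.0 SC2=CD1,NE1,CE2@2.3 SC3=CD2,CE3@2.3 SC4=CZ2,CH2,CZ3@2.3
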