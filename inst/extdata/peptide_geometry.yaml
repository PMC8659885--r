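# Ideal peptide geometry (Engh-Huber-style averages), frozen so that the
# synthetic-structure generators are bit-stable across releases.
# Lengths in Angstrom, angles in degrees.
bonds:
  N_CA: 1.458
  CA_C: 1.525
  C_N: 1.329
  C_O: 1.231
  N_H: 1.010
angles:
  N_CA_C: 111.0
  CA_C_N: 116.2
  C_N_CA: 121.7
  CA_C_O: 120.5
  O_C_N: 123.3
  C_N_H: 119.0
  H_N_CA: 119.3
omega: 180.0
conformations:
  helix: {phi: -57.0, psi: -47.0}
  extended: {phi: 180.0, psi: 180.0}
# relative half-width of bonded distance-range constraints
delta:
  covalent: 0.02
  angle: 0.05
  dihedral: 0.07
  sidechain_link: 0.25
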