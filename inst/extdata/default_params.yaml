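# Default force-field parameter tables.
#
# All energies are in reduced units of the thermal energy scale (kT = 1 at the
# reference temperature); lengths in Angstrom.  The van der Waals and
# solvation channels are generated from these per-type tables and discretized
# onto a small number of shells; externally supplied step-potential tables in
# the same layout are accepted verbatim.
kinds:                      # backbone particles: mass (amu), hard-core radius
  "N":  {mass: 14.007, radius: 1.32}
  "H":  {mass: 1.008,  radius: 0.90}
  "CA": {mass: 12.011, radius: 1.35}
  "C":  {mass: 12.011, radius: 1.40}
  "O":  {mass: 15.999, radius: 0.90}
sidechain:
  radius_base: 1.70         # bead radius = base + per_atom * (heavy atoms)
  radius_per_atom: 0.22
vdw:
  eps0: 1.0                 # well-depth scale for the most hydrophobic pair
  # shell boundaries in units of the contact distance sigma = r_i + r_j; the
  # innermost shell is a hard core placed at sigma itself, so every finite
  # shell averages the attractive branch of the continuous well (no spurious
  # entry barrier from averaging the repulsive wall into a shell)
  shell_scheme: [1.00, 1.12, 1.35, 1.60, 1.90]
solvation:
  s0: 0.35                  # desolvation (burial) penalty scale, positive
  decay: 0.25               # exponential range in units of sigma
hbond:
  r_min: 1.8                # H...O well, Angstrom
  r_max: 2.6
  gate_min: 2.7             # auxiliary N...O linearity gate, Angstrom
  gate_max: 3.6
  eps: 4.0                  # well depth before the w_hb weight
# Kyte-Doolittle hydropathy, mapped internally to [0.2, 1] for well depths
hydropathy:
  ILE: 4.5
  VAL: 4.2
  LEU: 3.8
  PHE: 2.8
  CYS: 2.5
  MET: 1.9
  ALA: 1.8
  GLY: -0.4
  THR: -0.7
  SER: -0.8
  TRP: -0.9
  TYR: -1.3
  PRO: -1.6
  HIS: -3.2
  GLU: -3.5
  GLN: -3.5
  ASP: -3.5
  ASN: -3.5
  LYS: -3.9
  ARG: -4.5
# The three named parametrizations.  `original` is the neutral reference;
# `new` adds extra hydrophobicity for sequence-local pairs (which favors
# local hydrogen bonding and helix formation); `enhanced_hb` additionally
# raises the hydrogen-bond energy and slightly raises the vdW weight.
presets:
  original:    {w_vdw: 1.00, w_solv: 1.0, w_hb: 1.0, local_scale: 1.0, local_window: 4, kT: 1.0}
  new:         {w_vdw: 1.00, w_solv: 1.0, w_hb: 1.0, local_scale: 1.5, local_window: 4, kT: 1.0}
  enhanced_hb: {w_vdw: 1.05, w_solv: 1.0, w_hb: 1.5, local_scale: 1.5, local_window: 4, kT: 1.0}
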