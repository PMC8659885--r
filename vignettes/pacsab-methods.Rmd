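---
title: "Model and methods: coarse-grained event-driven protein dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: coarse-grained event-driven protein dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsab)
```

## The model

`pacsab` implements an implicit-solvent coarse-grained protein model with an
atomistic backbone: every residue carries the particles N, H, CA, C and O
(no amide H for proline), so that backbone hydrogen bonding — which shapes
the ensembles of disordered proteins — can be represented explicitly, while
side chains are reduced to 0–4 beads following a MARTINI 2.x-style mapping
(glycine and alanine none; most residues one bead; lysine/arginine two;
histidine, phenylalanine, tyrosine three; tryptophan four).  The
atom-to-bead assignment ships as a plain-text table
(`inst/extdata/sidechain_map.txt`) so it can be corrected without code
changes.  Bead masses are sums of the mapped heavy-atom masses, so the total
chain mass is preserved.

The pairwise potential combines two channels with tunable weights,

$$V(r_{ij}) = \omega_{vdW}\, V_{vdW}(r_{ij}) + \omega_{solv}\, V_{solv}(r_{ij}),$$

where $V_{vdW}$ is an attractive van der Waals-like well and $V_{solv}$ a
positive, shorter-ranged desolvation (burial) penalty.  Hydrophobicity of
the force field increases with $\omega_{vdW}$ and decreases with
$\omega_{solv}$.  The continuous channel shapes are generated by the
package — a Lennard-Jones form with per-pair contact distance
$\sigma_{ij} = r_i + r_j$ and well depth from an interpolated Kyte–Doolittle
hydrophobicity scale, and an exponentially decaying burial penalty — and
externally supplied step-potential tables in the same layout are accepted
verbatim.  The two-weight combination law, the discretization and the
engine are the contract; the exact tables are replaceable data.

Because the dynamics is event-driven, every interaction is discretized into
a small number of spherical shells (`discretize()`), each shell carrying
the uniform-in-$r$ average of the continuous potential.  The shell
boundaries sit at $\{1.00, 1.12, 1.35, 1.60, 1.90\}\,\sigma$ with a hard
core below the first boundary.  Placing the innermost boundary at $\sigma$
itself matters: averaging the steep repulsive branch into a finite shell
would create a spurious entry barrier that grows with the well depth and
inverts association trends, so every finite shell averages only the
attractive branch.

Three named parametrizations are shipped: `original` (neutral reference),
`new` (sequence-local pairs within 4 residues get their attractive shells
multiplied by `local_scale` = 1.5, favouring local hydrogen bonds and
helix), and `enhanced_hb` (additionally raises the hydrogen-bond weight by
50% and the vdW weight by 5%).  All weights are relative multipliers on the
base tables, not absolute claims about any published parameter set.

## Hydrogen bonds

Every backbone amide H (donor, residue $i$) and carbonyl O (acceptor,
residue $j$) with $|i-j| \ge 2$ or on different chains interacts through an
attractive well of depth $w_{hb}\,\varepsilon_{hb}$ (default
$\varepsilon_{hb} = 4$ energy units) on the H···O distance over
[1.8 Å, 2.6 Å], conditional on the auxiliary N···O distance lying inside
[2.7 Å, 3.6 Å] (a linearity gate).  Bonds are *saturating*: at most one
formed bond per donor and per acceptor, as for real amide hydrogen bonds.
Saturation is what makes secondary structure protective — a helically
satisfied carbonyl cannot simultaneously accept an intermolecular bond —
and without it helix formation barely affects association.  The gate and
the partners' availability are evaluated at the instant the H···O pair
crosses the well boundary: the energy step is applied only if the bond can
form, and the pair's bonded state is recorded so that every energy change
in the simulation is an explicit impulse.  This keeps total
energy exactly conserved while retaining the directional character of the
bond; the alternative — re-predicting H···O events whenever the gate pair
crosses its range — would couple three-body bookkeeping into the event queue
for no measurable benefit at these system sizes.  Setting `w_hb = 0`
removes the wells entirely ("unplugged" hydrogen bonding); the H/O
particles then fall back to the same inner hard wall through the generic
pair table, so the trajectory is independent of the hydrogen-bond machinery.

## Bonded geometry as distance ranges

Event-driven dynamics has no continuous forces, so all bonded geometry is
encoded as distance ranges acting as reflecting walls: covalent bonds as
$[d_0(1-\delta), d_0(1+\delta)]$ with $\delta = 0.02$; bond angles as 1–3
ranges with $\delta = 0.05$; the trans peptide bond as a CA–CA 1–4 range;
and backbone dihedral freedom as 1–4 ranges wide enough to admit both the
helical ($\phi = -57°$, $\psi = -47°$) and extended ($\phi = \psi = 180°$)
conformations, computed from the frozen ideal-geometry table
(`inst/extdata/peptide_geometry.yaml`).  Side-chain links use looser
ranges ($\pm 25\%$) since bead positions average several atoms.  Nonbonded
exclusions follow the standard 1-2/1-3/1-4 set; backbone 1-4 geometry is
governed by the dihedral ranges, and excluded-volume-only pairs use a
contact distance softened by 0.8 so that ideal backbone geometry never
starts inside a core.

Restraints reuse the same mechanism: `native`, `freeze` and `relax` modes
place a range $[d(1-0.05), d(1+0.05)]$ around every current CA–CA distance
of the selection; `helix` mode places ranges ($\pm 8\%$) around the ideal
helix distances for (i, i+2), (i, i+3), (i, i+4) CA pairs.  Residue ranges
are 1-based and inclusive throughout the package.

## The engine

Between events particles fly ballistically; at an event the radial relative
velocity either refracts across the energy step
($v_r' = \mathrm{sign}(v_r)\sqrt{v_r^2 - 2\Delta U/\mu}$, when the radial
kinetic energy exceeds the step) or reflects ($v_r' = -v_r$), conserving
momentum and energy exactly.  Bookkeeping is standard event-driven
practice: a binary heap with lazy invalidation via per-particle collision
counters and periodic compaction; ties broken in (time, i, j) order for
determinism; per-particle local clocks, so a particle's position is
advanced only at its own events and stored frames are pure extrapolations —
trajectories are therefore bit-identical regardless of the snapshot
interval.  The thermostat is Andersen-style: a Poisson process (default
0.1 collisions per particle per time unit) resamples one particle's
velocity from the Maxwell–Boltzmann distribution; rate 0 gives
microcanonical dynamics.

Instead of cell lists, the engine re-predicts all pairs involving a
particle after each of its events and schedules a periodic global
re-prediction ("resync") event that also refreshes minimum-image
assumptions in periodic boxes; the resync interval is derived from the box
margin beyond the largest cutoff and a generous bound on particle speeds.
At the system sizes this package targets (two chains, at most a few
hundred particles) this is simpler than cell lists, deterministic, and not
the bottleneck — the event budget is dominated by bond-range bounces.

Units are reduced: lengths in Å, masses in amu, energies in units of the
reference thermal energy ($k_BT = 1$ in the default parametrization), and
time in Å·(amu/energy)$^{1/2}$.  No attempt is made to calibrate reduced
time against physical microseconds; the package reports event counts and
reduced times.

## Protocols

A protein solution is modelled as two molecules in a cubic periodic box
whose side sets the concentration, $C = 2/L^3$:
`box_for_concentration(2, 30e-6)` gives the 48 nm box at which two peptides
correspond to 30 µM (such a box would hold about 3.7 million water
molecules — `estimate_water_count(48)` — which is why an implicit-solvent
treatment is used in the first place).  Replicas start from random rigid
poses with a minimum separation beyond all cutoffs (`place_replicas`),
complexes are relaxed under all-CA restraints before stability runs
(`relax_complex`), and `scan_parameter` runs a replica set per parameter
value with common seeds for variance reduction.  Stationary averages
discard the first 25% of each trajectory (`burn_in = 0.25`), the
operational meaning of "after the stationary regime is reached" here.

A note on encounter-rate arithmetic: with a diffusion-limited rate constant
of order $10^8\ \mathrm{s^{-1}M^{-1}}$, the mean association waiting time at
concentration $C$ is $1/(kC)$ — about 333 µs at 30 µM, not tens of
microseconds; the package exposes the formula rather than reproducing any
shorter printed figure.

## Observables

* `monomer_fraction` / `stationary_monomer_pct`: a frame's two molecules
  count as a dimer when the minimum inter-chain particle distance
  (minimum image) is below the association cutoff, default 8 Å.  The
  association criterion is deliberately a threshold on the same
  minimum-distance curve that the trajectory figures plot; the cutoff is
  configurable and results should be checked for sensitivity to it.
  Frames are pooled into time bins across replicas; empty bins are
  missing, not zero.
* `contact_map`: residue-level any-particle contacts, default cutoff
  6.5 Å, with an `interface_mask` helper for annotating binding-interface
  segments such as the β-sheet face of ubiquitin (residues 4–12, 42–51,
  62–71).
* `radius_of_gyration`: mass-weighted, reported in nm.
* `helicity`: residue $i$ is helical when the (i, i+4) backbone hydrogen
  bond geometry (H···O < 2.6 Å and N···O < 3.6 Å) holds for $i$ or
  $i-4$.  Because published helicity percentages rarely state their
  criterion, a dihedral-window alternative (`helicity_dihedral`,
  $\phi \in [-100°, -30°]$, $\psi \in [-80°, -5°]$) is provided and the two
  agree within one residue on the fixtures.
* `rmsd`: Kabsch least-squares superposition (proper rotations only) on an
  alignment selection, measured over a possibly different selection — for
  complex analyses align on the frozen receptor CA and measure over all
  complex CA.
* `dissociation_fraction`: fraction of replicas currently unbound; no
  monotone smoothing, re-binding counts.
* `cluster_frames`: leader clustering (first cluster within the RMSD
  cutoff wins, default 5 Å), chosen for determinism and streaming;
  medoid centers are recomputed once at the end.

## Synthetic fixtures and what the tests do (and do not) show

All tests run offline on generated structures: extended chains
($\phi = \psi = 180°$; ~3.6 Å/residue end-to-end growth), ideal helices
($\phi = -57°$, $\psi = -47°$; 1.5 Å/residue rise, every interior
(i, i+4) H···O pair inside the hydrogen-bond well), two-particle
square-well systems with closed-form bound-orbit periods and two-state
occupancies, and an aggregating homopolymer pair.

The aggregation toy is the desk-scale stand-in for two-peptide
oligomerization runs: two leucine 7-mers in a 54 Å periodic box (a
concentration vastly above the experimental µM regime, so that encounters
happen within affordable trajectories), side-chain well depth set directly
by `stickiness` (default 0.4 energy units — deliberately marginal, so that
both the hydrophobicity and the hydrogen-bond channels matter), solvation
channel off so stickiness is the only attraction knob besides hydrogen
bonds, and thermostat coupling weakened to 0.005–0.01 collisions per
particle per time unit during aggregation runs so diffusive search is not
throttled.  With these conditions the stationary monomer percentage
decreases with the hydrophobicity multiplier, and chains whose central
segment is restrained to the helix (and which therefore satisfy their
backbone donors/acceptors internally) stay monomeric more than extended
chains — the same direction as the full model's behaviour.  What these
tests show is that the *mechanisms* (hydrophobicity-driven association;
helix structure suppressing backbone-zipper association) are present and
correctly signed in the implementation; they do not show that any
particular real peptide's monomer percentage is reproduced, which would
require the unpublished per-type interaction tables and multi-microsecond
sampling.

## Numerical choices

* Event-time roots are computed sign-aware (approach/recede), which makes
  post-event re-prediction robust without epsilon nudges; events closer
  than the tie-break tolerance are serialized deterministically.
* Total energy is tracked incrementally (every change is an impulse) and
  cross-checked against a from-scratch recomputation; microcanonical
  drift over $10^5$ events is at the $10^{-15}$ level, far below the
  $10^{-8}$ contract.
* The problem sizes used in the shipped checks — 5–20-residue chains,
  $10^5$-event conservation runs, 6–10 replicas of a few thousand reduced
  time units — were chosen as the smallest systems in which each property
  is meaningfully exercised.
* Degenerate inputs: proline contributes no donor; chains shorter than 5
  residues reject helicity; collinear alignment selections reject RMSD;
  overlapping starts reject the run with the offending pair named.

## Known limitations

* The per-type-pair step-potential tables are generated defaults, not a
  published parameter set; quantitative agreement with any specific
  published parametrization is out of scope.  External tables are accepted.
* No electrostatics channel, pH/salt dependence, or lipid bead types.
* Amide hydrogens missing from experimental PDB files are rebuilt from
  local geometry rather than rejected (the only deviation from a strict
  "missing backbone atom" error, since X-ray structures essentially never
  deposit them).
* The binary trajectory format stores float64 coordinates; at typical box
  sizes float32 would not meet a 10^-6 Å round-trip contract.
* Physical-time calibration, replica exchange, free-energy estimators and
  fibril structure are out of scope.
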