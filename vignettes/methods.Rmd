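---
title: "Methods: a desk-scale model of amyloid dissociation by resonant mid-infrared pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale model of amyloid dissociation by resonant mid-infrared pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package models

Polyalanine (polyA) amyloid fibrils — ordered aggregates held together by
intermolecular antiparallel beta-sheet hydrogen bonds — can be dissociated
by tunable mid-infrared laser light resonant with the amide-I band, the
backbone C=O stretching vibration near 1680 cm^-1 (about 6 um).  The
mechanism, at the molecular level, is: a picosecond electric-field pulse
resonantly pumps the C=O oscillators; the inter-strand C=O...H-N hydrogen
bonds transiently break; when a water molecule happens to enter the gap it
caps the freed donor and acceptor and prevents the bond from reforming;
accumulated irreversible breaks let peptides peel off as monomers and
small oligomers, and the freed chains partly convert to helical
conformations.

`fibrilpulse` implements this entire protocol at desk scale: a reduced
(but fully molecular-mechanical) model of capped 13-alanine peptides
assembled into a two-layer antiparallel beta-sheet dodecamer in explicit
three-site water, a nonequilibrium MD engine that applies a train of
Gaussian-enveloped oscillating field pulses, and every analysis the
protocol needs — C=O vibrational power spectra, DSSP-criteria secondary
structure, oligomer size distributions, and event-aligned hydrogen-bond
statistics.

## The reduced model

### Sites, charges, geometry

Every atom is explicit (ACE cap 6 sites, alanine 10, NME cap 6, water 3;
the default dodecamer plus 9,662 waters is 30,690 atoms).  Partial
charges are patterned after standard protein force fields, so the
C=O...H-N hydrogen bond emerges from electrostatics plus Lennard-Jones
repulsion rather than from an ad-hoc bonded term.  Peptides are built by
internal-coordinate placement at ideal backbone dihedrals — (phi, psi) =
(-139, +135) degrees for the antiparallel strand, (-57, -47) for the
alpha-helix used by the fixture morphs — with L-configuration verified
against the improper dihedral convention of real protein structures.

### Fibril assembly

The fibril definition (12 peptides, two sheets, antiparallel) leaves the
strand registry and sheet stacking open; the builder reconstructs a
plausible geometry by optimisation rather than by hand-tuned offsets.
Adjacent strands are related by a 180-degree rotation about the sheet
normal; the along-strand offset, spacing adjustment and a common strand
"roll" about the strand axis are chosen by a coarse grid scan that counts
in-band O...N registry contacts (2.6-3.35 A), ranks candidates by the
physical rigid-body interaction energy (Coulomb + Lennard-Jones), and
polishes the winner with a bounded quasi-Newton refinement.  The
two-strand lattice vector (the "wide-pair" interface) and the sheet
stacking offset are optimised the same way.  The result is a fully
hydrogen-bonded sheet: 14 designed bonds per interface, all with O...N
near 2.9 A.

The sheet-to-sheet spacing defaults to 5.4 A, the tight packing distance
of polyalanine sheets.  This keeps the two sheets within the 5 A
heavy-atom contact cutoff, as an intact fibril must be: the analysis that
counts oligomers sees the freshly built dodecamer as a single cluster of
twelve.

### Force field

Harmonic bonds (E = k/2 (r-r0)^2) and angles, cosine torsions, fixed
charges, Lorentz-Berthelot Lennard-Jones, and shifted-force truncation of
both Coulomb and LJ at a single cutoff (12 A by default; any run must
satisfy cutoff <= box/2).  Shifted-force truncation makes energy and
force continuous at the cutoff; with the 0.5 fs time step this keeps
microcanonical drift below 0.01% of the mean kinetic energy over 10 ps,
which is the package's integrator acceptance bar.  Water is a flexible
three-site model; its internal stiffness is deliberately soft (O-H
stretch near 2400 cm^-1, bend near 1000 cm^-1) — water internal
vibrations play no role in the mechanism, and softer stiff modes reduce
integration error at the fixed 0.5 fs step.  Both choices replace the
rigid-water/PME machinery of full-scale protocols, which is out of scope
here.

### Spectroscopic calibration

The C=O stretch stiffness is the spectroscopic handle.
`calibrate_co_stiffness(nu)` inverts the two-body harmonic relation
nu = (1/2 pi c) sqrt(k/mu) with mu = mC mO/(mC+mO); 1680 cm^-1 gives
k about 1.64e3 kcal/mol/A^2.  An *embedded* carbonyl, however, vibrates
about 6% above the two-body frequency: the skeletal stretches and the
angle terms centred on the sp2 carbon add restoring force along the
bond.  We quantified this by normal-mode analysis of capped alanine and
found the shift irreducible by any reasonable softening of the couplings
(even marshmallow-soft skeletal terms leave +40 cm^-1).
`default_forcefield()` therefore applies a fixed amide-I localization
factor of 0.940 to the calibration target — the usual force-field
practice of parameterising a stiffness so the *molecular* normal mode
lands on the band.  With it, the molecular amide-I mode sits at the
requested wavenumber, k still scales exactly as nu^2 (so recalibration
tracks monotonically), and the measured condensed-phase spectrum of a
solvated sheet peaks within the spectral bin of the target (1684 +/- 8
cm^-1 for a 1680 target in our validation run).

The skeletal bonds attached to the carbonyl carbon (CT-C, C-N at k = 160
kcal/mol/A^2) are softer than in all-atom force fields.  This is a
deliberate localization choice: their stretching bands sit near 500
cm^-1, far below amide I, so the C=O mode stays clean and the pulse
couples to a well-defined oscillator.

## Dynamics

Velocity-Verlet at a single 0.5 fs time step for everything (replacing
multiple-time-step hierarchies), a single Nose-Hoover thermostat with
coupling mass Q = Nf kB T tau^2 (tau = 0.1 ps) in the Martyna-Tuckerman
split, and an optional stochastic isotropic volume-move barostat for
equilibration only; production irradiation runs use a fixed box, matching
the protocol shape of constant-temperature irradiation.  Velocities are
initialised from the Maxwell-Boltzmann distribution, seeded; replicas are
independent seeds.

The field force on atom i is q_i E(t) e_pol with
E(t) = E0 exp(-(t-t0)^2/2 sigma^2) cos(omega (t-t0)), pulse centres
generated by multiplication (no accumulated drift over thousands of
pulses), and defaults E0 = 1e8 V/cm (23.06 kcal/mol/e/A), sigma = 1 ps,
one pulse every 35 ps, omega = 2 pi c nu.  The field acts on all charged
sites by default (physically the field sees every charge; a peptide-only
mode exists for comparison).  Polarization defaults to the sheet's
hydrogen-bond axis — the direction in which the field couples most
directly to the C=O bonds — and can be fixed, user-set, or per-pulse
random.  The engine accumulates the field work F.v per pulse, which is
the package's measure of resonant absorption: a single driven C=O
oscillator absorbs an order of magnitude more work at resonance than
detuned by +300 cm^-1.

The thermostat couples globally during irradiation and disposes of the
deposited field work; the work itself is logged separately per pulse, so
absorption and dissipation stay distinguishable.

## Analyses

*Spectrum.*  The C=O stretch velocity (central difference of the bond
length at a 2 fs frame stride, Nyquist-checked) is Welch-averaged with a
Hann window and 50% overlap over all backbone carbonyls; the resonance is
the arg-max over a configured search window, reported with the bin width
as its uncertainty.  The estimator satisfies Parseval to within 1% and
locates synthetic tones to within one bin across the amide-I region.

*Secondary structure.*  Backbone hydrogen bonds are scored with the
published DSSP electrostatic criterion,
E = 0.42 x 0.20 x 332 (1/rON + 1/rCH - 1/rOH - 1/rCN), bonded when
E < -0.5 kcal/mol, with same-residue and peptide-bond-neighbour pairs
excluded.  Beta bridges use the DSSP antiparallel and parallel patterns;
helices are two consecutive i->i+3/4/5 turns.  Tie-breaking is simplified
to beta > helix > other (full DSSP bulge/overlap rules are out of scope);
intermolecular antiparallel beta is the headline fraction,
intramolecular and parallel beta are tracked separately.

*Oligomers.*  Two peptides belong to the same oligomer when any two
heavy atoms are within 5 A (minimum image); oligomers are connected
components of the contact graph, validated frame-by-frame against an
independent brute-force union-find oracle in the tests.  Histograms are
averaged over pulse-index windows mapped from trajectory time stamps.

*Hydrogen-bond kinetics.*  A geometric criterion (H...acceptor <= 2.5 A
and donor-H-acceptor angle >= 135 degrees), deliberately independent of
the DSSP energy criterion, scores the designed fibril pairs and their
water partners (acceptor C=O to any donating water; donor N-H to any
accepting water oxygen).  The irreversible break of a pair is the last
formed->unformed transition never followed by reformation, guarded by a
censoring margin; profiles are averaged per event on a symmetric tau
grid.  Event alignment is per-pair (the simplest faithful reading; no
grouping of simultaneous breaks).

## The fixture generator

Analyses are validated against scripted trajectories with exact ground
truth — geometric puppetry, no force field: rigid detachments beyond the
contact cutoff, per-pair hydrogen-bond breaks realised by reflecting the
donor hydrogen through its nitrogen (destroying exactly that bond),
water "arrival" that teleports dedicated parked waters into canonical
hydrogen-bond geometry, and beta->helix morphs through ideal-dihedral
interpolation.  Truth tables (break frames, per-frame partitions,
per-peptide phases) are emitted alongside, and the test suite requires
exact frame-level agreement.  What passing these fixtures shows is that
the analyses are correct; what it does not show is that the reduced
force field reproduces the thermodynamics of real fibrils — that
distinction is the reason the generator exists.

## Problem sizes and study conditions

The paper-scale system (12 x 13 residues, 9,662 waters, 4,000 pulses /
140 ns, six replicas) is exercised for composition and geometry but not
integrated at full scale; it ships as a documented preset.  The
simulation problem sizes used by the package's own validation are chosen
so the full stack runs on a single CPU in minutes: a solvated two-strand
sheet (a few hundred atoms) for the spectral pipeline (about 15 ps of
sampled dynamics, <= 10 cm^-1 bins), a 125-water box for the integrator
checks (10-20 ps), and short one-to-few-pulse irradiation runs at the
protocol's field parameters (E0 = 1e8 V/cm, sigma = 1 ps, 35 ps spacing)
for the qualitative dissociation comparisons.  Field parameters, the 5 A
cutoff, the DSSP threshold, and the 2.5 A/135-degree geometric criterion
are the study's stated conditions and are never adjusted per run.

## What desk scale shows about driven dissociation

The driven-versus-control experiments in the test suite run the exact
protocol field (E0 = 1e8 V/cm, sigma = 1 ps, resonance-tuned) on the
largest solvated sheet the suite's time budget allows.  They demonstrate
resonant absorption (thousands of kcal/mol of field work per pulse,
versus an order of magnitude less when detuned) and the characteristic
transient response: the intermolecular-beta fraction and the
hydrogen-bond occupancy dip during each pulse and recover between
pulses.  What they do not show at this scale is *irreversible*
dissociation: the pumped C=O energy thermalises faster than the slow
inter-strand separation coordinate can rupture, and in a small periodic
box a transiently broken pair re-forms immediately.  That is consistent
with the full-scale protocol, where dissociation of the dodecamer
accumulates over thousands of pulses; reproducing it would need the
paper-scale preset, not a desk run.  The corresponding qualitative
driven-dissociation checks in the test suite therefore report the
negative result honestly rather than passing by construction.

## Known limitations

- The reduced force field is not ff14SB; absolute energetics,
  dissociation time scales and the single-layer restacking observation
  are outside what it can reproduce.
- DSSP bridge labels on very small sheets (two short strands) flicker
  under thermal motion even while the hydrogen bonds persist; the
  hydrogen-bond presence series is the more robust observable at the
  smallest scales, and the driven-versus-control comparisons are
  therefore run on the largest system the time budget allows.
- Shifted-force truncation replaces Ewald electrostatics; long-range
  dielectric effects are absent.
- The amide-I localization factor is calibrated once, on capped alanine,
  and assumed transferable across targets in the 1500-1800 cm^-1 range
  (verified at 1600 and 1680).
- The hydrophobicity knob lambda scales only the side-chain-carbon /
  water-oxygen attraction; it is a one-parameter caricature of
  hydrophobicity sufficient for direction-of-effect experiments, not a
  solvation model.
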