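---
title: "Measuring uracil base flipping and its recognition by UDG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring uracil base flipping and its recognition by UDG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseflip)
```

## The problem

Uracil-DNA glycosylase (UDG) initiates base-excision repair by excising
uracil from double-stranded DNA, but it can only act on a base that has
rotated out of the helical stack into an extrahelical state. Whether a
spontaneously (or mechanically) flipped-out uracil is *presentable* to UDG
is a geometric question: how far has the base rotated, which groove did it
leave through, and how much room does the opposite strand's backbone leave
around it? This package implements the quantitative machinery for that
question: collective coordinates that measure the flip, accessibility and
hydrogen-bond distances, base-pair deformation parameters, an evaluation
protocol for rigid docking poses against a reference recognition complex,
and a desk-scale metadynamics engine that reconstructs free-energy profiles
along the flipping coordinate.

## Flipping coordinates

The flip angle is a center-of-mass pseudo-dihedral: four atom groups
P1-P4 are reduced to their centers of mass and the signed dihedral
P1-P2-P3-P4 is taken, with the P2-P3 line as the rotation axis. Three
group schemes are implemented:

* **CPD** - P1: base of the neighboring nucleotide plus the base opposing
  that neighbor; P2: sugar of the neighbor; P3: sugar of the flipping
  nucleotide; P4: the target base.
* **CPDa** - P1: all four bases of the two flanking pairs; P2/P3: the
  flanking sugars; P4: the target base.
* **CPDb** - P1 as CPDa; P2/P3: the flanking phosphate groups (P, OP1,
  OP2, O5' of the target residue and of its 3' neighbor); P4: the target
  base.

Angles are reported in (-180, 180], ties at +-180 mapping to +180. The sign
convention is anchored on the duplex builder: a rotation that carries the
base into the major groove (the +x side of the base-pair standard frame)
gives positive angles, consistently for CPD and CPDb.

Two conventions were genuinely open and were fixed empirically:

* **Which neighbor is the CPD "next" nucleotide.** With the 5'-side
  neighbor, CPD and CPDb agree in sign (+ = major groove) and the
  intrahelical CPD minimum of the ideal duplex sits near +35 degrees, in
  the range reported for equilibrium ensembles of this coordinate; the
  3'-side choice inverts the CPD sign. The 5' side is therefore the
  default, switchable via `cpd_neighbor`.
* **Dihedral ordering.** P4 is always the target base and P2-P3 the
  backbone anchor; this makes `apply_base_flip` exact, because rotating
  the base rigidly about the P2-P3 line changes the coordinate by exactly
  the rotation angle.

The accessibility proxy `u_groove_distance` is the minimum distance from
the uracil N1 atom to any phosphorus of the opposite strand. Watson-Crick
integrity is tracked by the hydrogen distances N1(A)...H3(U) and
O4(U)...H61(A).

## Pair-center distance: which "center of mass"?

The distance between the centers of the paired uracil and adenine residues
is a common flip-progress readout, but the selection and weighting behind
such numbers are rarely stated. On an idealized B-form duplex the candidate
conventions separate cleanly: mass-weighted heavy-atom whole-nucleotide
centers give 11.1-11.7 Angstrom across the entire canonical backbone-torsion
range (the phosphate group, heavy and far from the axis, dominates), while
the unweighted all-atom center of the whole residue - the default of the
widely used MD visualization toolchain - gives about 10.3 Angstrom, matching
the ~10.5 Angstrom initial-state value reported for this system.
`pair_com_distance` therefore defaults to unweighted whole-residue centers
and exposes `weighting = "mass"` and `atoms = "base"` for sensitivity
analysis. `center_of_mass` itself defaults to mass weighting, as its name
promises.

## The synthetic duplex builder

`build_duplex` generates an idealized B-form duplex for arbitrary sequence.
Base rings are placed from the standard (Tsukuba-convention) base
reference-frame coordinates, in which a Watson-Crick partner is the
(x, -y, -z) image; pair frames are propagated along the helix through
rigid-body step parameters (uniform twist 36 degrees and rise 3.38 Angstrom
by default, per-step overrides available). The sugar-phosphate backbone is
rebuilt per nucleotide from internal coordinates: glycosidic chi = -98
degrees (anti), a C2'-endo sugar (pseudorotation phase 162 degrees,
amplitude 38 degrees), gamma = 54, beta = 171 degrees, with branch
chirality taken from the idealized residue geometries of the PDB Chemical
Component Dictionary (shipped as a plain-text table). These are canonical
fiber-B values chosen a priori; the resulting duplex has phosphorus at 8.9
Angstrom radius, successive P-P distances of 6.4-6.5 Angstrom and a
minor-groove cross-strand P-P separation near 11 Angstrom, all in the
textbook B-DNA range. Base hydrogens are placed (in-plane, from the CCD
geometry); sugar hydrogens are omitted - no implemented measurement uses
them.

Because the builder propagates pair frames with the same mid-frame algebra
the analyzer inverts, builder -> `base_pair_parameters` /
`step_parameters` round trips are exact to floating-point, which the test
suite exploits (recovery to 0.5 degrees / 0.05 Angstrom including
deliberately non-uniform steps).

`apply_base_flip` rotates only the base moiety about the active scheme's
P2-P3 axis. Real flips, generated by molecular dynamics, distort the
backbone as well; synthetic flipped states are labelled with a
`"synthetic"` provenance attribute and should be read as controlled
geometry probes, not as physical flip intermediates.

## Docking-pose evaluation

A pose is scored by `uracil_similarity_distance`: the pose receptor is
superposed onto the reference receptor by a Kabsch fit on C-alpha atoms of
residues shared by number, the transform is applied to the whole pose, and
the distance between the two uracil N3 atoms is returned. The best
(minimum) distance over a pose set is classified High (< 3 Angstrom),
Medium ([3, 6)), Low ([6, 9)) or None (>= 9); the published rule uses
strict inequalities, leaving the boundaries unassigned, and the package
deterministically assigns each boundary to the worse class. The 15
Angstrom cutoff is a retention/display filter only - classification always
uses the unfiltered minimum. The quaternion (Horn) superposition method
serves as an independent oracle for the Kabsch fit in the tests, never as
the implementation.

Synthetic pose sets draw rotations from an axis-angle distribution (axis
uniform, angle |N(0, scale^2)|) about the DNA centroid and translations
N(0, scale^2/3) per component; pose 0 is always the identity so every set
contains its own ground truth. The mock receptor is a rigid C-alpha cloud
with a marker atom at a known offset from the uracil N3, which makes
alignment-invariance and rank-fidelity properties testable without any
external structure.

## Metadynamics toy

The 1D engine runs overdamped Langevin dynamics on a periodic coordinate
(degrees on the circle), with Gaussian hills deposited at the walker
position: hill weight 0.001 kcal/mol, width two 5-degree bins, deposition
every 25 steps, 310 K (kT = 0.616 kcal/mol). "Width = 2 bins" is read as
the Gaussian sigma (10 degrees); `width_is_sigma = FALSE` selects the FWHM
reading instead. Standard (not well-tempered) metadynamics is used, since
the production settings specify a fixed hill weight. The PMF estimator is
the negative accumulated bias on the 5-degree grid, min-shifted to zero.

Numerical choices: the bias is accumulated on a 1-degree force grid with
linear interpolation (the deposition loop is the only compiled code in the
package); friction 0.001 kcal/mol ps/deg^2 and a 1 fs step give an RMS
thermal step of about 1.1 degrees; a step exceeding 90 degrees aborts with
a stability error. The default 4e6 steps deposit 160,000 hills, which the
convergence tests show is enough to read an 8.2 kcal/mol barrier back to
within a few percent; these desk-scale sizes keep a full run in seconds.
The toy demonstrates the estimator's machinery on designed surfaces - it
does not, and is not meant to, reproduce the solvated all-atom free-energy
landscape of a real oligomer.

## Trajectory descriptors

Multi-model PDB files act as trajectories. `rmsd_series` Kabsch-fits each
frame to a reference frame on the selection; `rg_series` is mass-weighted
by default; `rmsf_profile` fits frames to the evolving mean structure (two
passes) and aggregates per residue, with an optional separate fit
selection. The RMSF reference (the time-mean structure) is a documented
choice; production analyses sometimes use the first frame instead.

## Reference-complex measurements

All measurements run unchanged on crystal structures: residue-name
dialects (DA/DT/.../THY/URA, one-letter codes) are canonicalized, the
uracil-analog list (2'-deoxypseudouridine and relatives) is configurable,
and base-frame fitting tolerates C-linked analogs by fitting on the ring
atoms present. The crystal recognition complex itself (PDB id 1EMH) is not
redistributable within the package; the acceptance test for its published
dihedral (-171.75 degrees) and groove distance (20.8 Angstrom) looks for a
locally supplied copy under `tests/testthat/fixtures/` and fails
otherwise, so that check is red in a fully offline environment while the
code path stays exercised by the synthetic structures.

## Known limitations

* Flipped synthetic states are pure base rotations; backbone relaxation,
  sequence-dependent steps and solvent are out of scope, so passing tests
  demonstrate correctness of the measurements, not realism of the
  intermediate structures.
* The duplex builder's backbone is helix-regular but not covalently
  continuous between residues (the O3'(i)-P(i+1) virtual bond is ~0.7
  Angstrom, not a bonded 1.6); no implemented measurement depends on bond
  topology.
* Base-pair parameters come from rigid base-frame fits and mid-frame
  decomposition; the full curvilinear-axis analysis of dedicated helix
  programs (groove widths/depths, bending profiles) is not reimplemented.
* The metadynamics engine is 1D (optionally interpretable per scheme); the
  production method's 2D (CPD, CPDb) landscape is outside the toy's scope.
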