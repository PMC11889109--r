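# baseflip

Geometry and docking analysis of uracil base flipping in double-stranded
DNA.

Uracil-DNA glycosylase (UDG), the first enzyme of the base-excision repair
pathway, can only excise a uracil that has rotated out of the DNA stack
into an extrahelical state. For structural biologists and molecular
modelers studying that recognition step, `baseflip` provides the
measurement layer: it quantifies *how far* a base has flipped, *which
groove* it left through, *how much room* the opposite strand leaves around
it, and *how closely* a docked UDG-DNA pose reproduces the crystallographic
recognition complex.

## What it computes

* **Flipping coordinate** — the center-of-mass pseudo-dihedral
  θ = ∠(P1, P2, P3, P4) over four COM groups, in the CPD, CPDa and CPDb
  scheme variants (base/sugar vs flanking-phosphate anchors), signed so
  θ > 0 means flipping through the major groove.
* **Accessibility and pairing** — d(U-groove) = min over opposite-strand
  phosphorus of |N1(U) − P|; Watson–Crick hydrogen distances
  N1(A)···H3(U) and O4(U)···H61(A); paired-residue center distance.
* **Base-pair geometry** — buckle/propeller/opening and
  tilt/roll/twist + shift/slide/rise from standard-reference-frame fits and
  mid-frame decomposition; global duplex bend.
* **Docking evaluation** — after Kabsch superposition of receptors,
  d(U1−U2) = |N3_pose − N3_ref|, pose retention below 15 Å, and the
  success classes High (< 3 Å), Medium (< 6), Low (< 9), None (≥ 9).
* **Metadynamics toy** — overdamped Langevin dynamics on a periodic 1D
  flipping coordinate with Gaussian hill deposition (0.001 kcal/mol hills,
  σ = 10°, 5° bins) and PMF reconstruction F(s) ≈ −V_bias(s).
* **Trajectory descriptors** — RMSD, radius of gyration (+ probability
  histogram), per-residue RMSF over multi-model PDB trajectories.

Everything is testable offline: a synthetic module builds idealized B-DNA
duplexes of arbitrary sequence, flips a base to any prescribed angle,
assembles mock receptor complexes and samples randomized rigid-body pose
sets with known ground truth.

## Worked example

```r
library(baseflip)

# the 17-mer flipping system: T12 -> U, standard B form
dna <- build_duplex("CAGGATGTATATATCTG", uracil_positions = 12)

pair_com_distance(dna, c("A", 12), c("B", 23))
#> [1] 10.33788
wc_hbond_distances(dna, c("A", 12), c("B", 23))
#>    N1_H3    O4_H6
#> 1.896751 2.070313

# flip the uracil 170 degrees into the major groove and re-measure
flipped <- apply_base_flip(dna, "A", 12, 170, groove = "major", scheme = "CPDb")
pseudo_dihedral(flipped, "A", 12, "CPDb")
#> [1] 170
u_groove_distance(flipped, "A", 12)
#> [1] 12.52209

# mock recognition complex + 1000-pose docking evaluation
cx <- build_mock_complex(flipped, seed = 11)
poses <- generate_pose_set(cx, 1000, displacement = 6, rotation = 25, seed = 12)
evaluate_pose_set(poses)
#> pose_evaluation: 1000 poses, 942 retained; best d_U1-U2 0.00 A (pose 0) -> High

# PMF reconstruction on a designed double well
run <- run_metadynamics(surface_double_well(8.2), metad_config(seed = 1))
pmf <- pmf_estimate(run)
pmf_barrier(pmf, at = 90)
#> [1] 7.997153
```

The paired-state numbers (center distance ≈ 10.3 Å, N1···H3 ≈ 1.9 Å) are
the intact-duplex baseline; flipping drives the hydrogen-bond distances
beyond 10 Å while the groove distance stays near 10–12 Å unless the
backbone also deforms. The identity pose anchors the docking evaluation at
d = 0 (class High), and the recovered PMF barrier is read directly off the
reconstructed profile.

A command-line wrapper with `build`, `flip`, `metrics`, `dockeval`,
`pipeline`, `metatoy` and `trajstats` subcommands is installed at
`inst/scripts/baseflip-cli.R`.

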