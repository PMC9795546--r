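---
title: "Geometric analysis of beta-hairpin conformer ensembles: methods and design"
author: "hairpintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric analysis of beta-hairpin conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpintools)
```

## Scope and model system

`hairpintools` analyses conformer ensembles of β-hairpin peptides, with
first-class support for backbone N-amination (hydrazino acids). The model
system is the 12-residue hairpin
H-Arg-Tyr-Val-Glu-Val-ᴅPro-Gly-Orn-Lys-Ile-Leu-Gln-NH₂: two antiparallel
strands joined by a ᴅ-Pro6–Gly7 turn, folded by the cross-strand backbone
hydrogen bonds 3NH–10O, 5NH–8O, 10NH–3O and 12NH–1O. All lengths are nm
and all angles degrees throughout; PDB Ångströms are converted at the I/O
boundary.

The package deliberately contains no molecular mechanics: it consumes
coordinate ensembles (multi-model PDB, or its own synthetic generator) and
computes geometric statistics. Producing physically realistic ensembles
(force fields, solvent, kinetics) is out of scope.

## Torsion angles and superposition

Dihedrals follow the IUPAC sign convention (cis = 0°, trans = 180°,
positive clockwise looking down the central bond), matching the standard
structural-biology toolkits, so φ/ψ of an α-helical ʟ-residue are
negative. The reference quadruple (0,0,0)–(1,0,0)–(1,1,0)–(1,1,1)
evaluates to +90°; the sign-flipped variant of the atan2 formula found in
some code bases gives −90° for the same points, so cross-tool comparisons
should check this case first. Collinear triplets raise a degenerate-
geometry error naming the offending atoms.

Superposition solves the orthogonal Procrustes problem by SVD with a
determinant correction excluding reflections (proper rotations only), after
centring both structures on the *selection* centroid — the package centres
on the selected atoms rather than the whole molecule, since the selection
defines the frame of interest (the 2–11 backbone window drops the frayed
termini). RMSD is reported for the selected atoms after the optimal fit.

## Internal-to-Cartesian chain building

`buildConformer()` grows the chain by natural-extension (NeRF) placement
using a fixed internal-geometry table: N–CA 0.147, CA–C 0.153, C–N 0.133,
C=O 0.123, N–H 0.100, N–NB 0.140, NB–HB 0.100 nm; backbone angles
N-CA-C 111°, CA-C-N 116°, C-N-CA 122°. These are standard peptide values;
only internal consistency matters for the geometric analyses built on top,
and the measured torsions of a built conformer reproduce the inputs to
better than 1e-6°. Chirality is set by the N-C-CA-CB placement torsion
(+120° for ʟ, −120° for ᴅ), which reproduces the ideal-residue value and
makes ᴅ-residues exact mirror images at CA.

N-amination replaces the amide H with a trigonal NB nitrogen in the
peptide-bond plane; HB1/HB2 complete a trigonal NH₂ whose plane sits at a
fixed rotation about the N–NB bond (torsion C(i−1)–N–NB–HB2 = 173°,
frozen; HB1 at +180° from HB2). This orientation lets the intraresidue C6
ring (NB–H···O=C, a six-membered ring) close in β-strand backbone
conformations, with HB2 serving the C6 contact and HB1 pointing to the
(i−2) carbonyl side — matching the field's naming of the two NH₂ donors.
Side chains beyond CB are not built; declared side-chain acceptors can be
stubbed as pseudo-atoms on the CA→CB direction and are documented as
approximations wherever they appear.

The C-terminal amide contributes its nitrogen (NT) so ψ of the last
residue is defined; its hydrogens are not modelled and it is never a
donor. The protonated N-terminus carries H1/H2/H3, reported separately as
donors (1NH1/1NH2/1NH3), never merged.

## Hydrogen bonds

Two geometric criteria are built in: **medium-strong** (hydrogen–acceptor
distance < 0.25 nm and donor–hydrogen–acceptor angle > 135°) and **weak**
(< 0.32 nm, > 90°). Both inequalities are strict — geometry exactly at a
threshold counts as absent — and the angle is measured at the hydrogen.
Medium-strong is strictly tighter, so every medium-strong bond is also a
weak bond; this nesting is asserted property-style in the tests.

Candidate donors are the backbone amide N–H, the N-terminal NH₃⁺
hydrogens, and NB–HB1/NB–HB2 of aminated residues (which have no amide H);
proline contributes no donor. Acceptors are the backbone carbonyl oxygens
plus any declared side-chain stubs. Intraresidue pairs are excluded except
NB–H→O(i), because the C6 bond is intraresidue by definition. Populations
are percentages of frames; a reporting threshold can drop low-population
rows, and NH₂ donors can optionally be collapsed to a single row carrying
the higher of the HB1/HB2 populations (the convention used when NH₂
groups are tabulated alongside amide donors).

## Turn typing, flips, twist, Ramachandran occupancy

Canonical centres: type I′ = (60°, 30°)/(90°, 0°) and type II′ =
(60°, −120°)/(−80°, 0°) for the turn's i+1/i+2 residues. The full
classifier takes the nearest centre in wrapped Euclidean distance over the
four angles, with a 60° radius beyond which frames are `other`; the radius
is a declared package constant (the canonical values are approximate
centres, and 60° comfortably separates the two centres, which are ~150°
apart, without absorbing strand geometry). A ψ-only classifier on the
turn's i+1 residue (nearer 30° → I′, nearer −120° → II′, boundaries at
the wrapped midpoints −45°/135° assigned to II′) reproduces the full
classifier on folded ensembles and is the one used for population
summaries. Note that extended/unfolded backbones (ψ ≈ 180°) also map to
II′ under the ψ-only rule — populations from mixed folded/unfolded
ensembles should be read accordingly.

Peptide-plane flips are counted as I′ ↔ II′ label changes after `other`
frames inherit the previous defined label. The default applies no
minimum-dwell smoothing (`debounce = 1`); on noisy label series this
over-counts relative to any smoothed convention, so a debounce parameter
is exposed.

The hairpin twist is the single cross-strand torsion over backbone atoms
1C–12N–8C–5N. Its mean is circular (resultant-vector direction): for
angle distributions clustered away from the ±180° seam this coincides
with the linear mean to well below 0.1°, and it remains meaningful across
the seam where the linear mean collapses. Torsion jitter propagates with
long lever arms into this metric, so even modest per-torsion noise widens
the twist distribution substantially.

Ramachandran regions are rectangular and versioned with the package:
β is φ ∈ (−180°, −45°) with ψ ∈ (45°, 180°] ∪ (−180°, −150°); α is
φ ∈ (−160°, −20°) with ψ ∈ (−120°, 30°); everything else is `other`. The
boxes do not overlap, fractions sum to one per residue, and the uniform-
angle occupancy of each box equals its area fraction (checked by
simulation).

## Daura clustering

Greedy medoid clustering over pairwise superposition RMSD of the selected
atoms (default: 2–11 backbone, 0.1 nm cutoff): the frame with the most
neighbours (strictly below the cutoff) becomes a medoid, it and its
neighbours are removed, and the procedure repeats. Neighbour-count ties
break towards the lowest pooled frame index — a documented, deterministic
choice. Cluster sizes are non-increasing by construction. Frames from
several trajectories are pooled with equal weight and each cluster reports
the percentage of every source's frames it contains, which is how folded
overlap between independent runs (and register-shifted misfolds populating
their own cluster) is diagnosed. Per-cluster hydrogen-bond signatures are
populations restricted to member frames.

The pairwise RMSD matrix is computed once (n² centred 3×3 SVD solves); at
the ensemble sizes used in the tests (≤ a few hundred frames after
subsampling) this is seconds. For much larger ensembles, subsample before
clustering.

## NOE back-calculation

Effective interproton distances are ⟨r⁻⁶⟩⁻¹/⁶ ensemble averages — the
average appropriate when molecular tumbling is fast relative to internal
motions, dominated by the frames where the pair is close. Pseudoatom
endpoints (groups of equivalent hydrogens, selected with a trailing `*`
wildcard) resolve to the group's geometric centre before distance
evaluation, and their restraints receive additive bound corrections from a
versioned table (methyl 0.10, methylene 0.09, NH₂ 0.10, aromatic 0.10 nm)
echoed in report headers. The violation of a restraint is
max(0, effective − (upper + correction)); the summary counts violations
strictly above a reporting threshold, 0.05 nm by default. Restraints
naming atoms the builder does not model are reported as unresolvable
rather than silently skipped.

## The synthetic ensemble generator

The generator is the package's stand-in for MD trajectories: a Markov
chain over conformational *state templates*, each a noiseless torsion set
plus a Gaussian jitter width, built into Cartesian frames. Five default
states model the hairpin study conditions:

* `folded_I`, `folded_II` — idealised hairpins with the canonical I′/II′
  turn and tuned antiparallel-β strand torsions;
* `frayed` — the folded-II′ core with residues 1, 2, 11, 12 re-drawn
  uniformly (terminal fraying), from a frozen seeded draw;
* `misfold` — the turn shifted one residue towards the N-terminus
  (register shift +1), which swaps the turn-flanking bond 8NH–5O for
  7NH–4O;
* `unfolded` — the extended chain with a wide jitter (default σ = 60°).

Strand torsions are a frozen per-residue template, tuned once against the
builder's internal geometry so that (i) the noiseless II′ template forms
all five cross-strand bonds under the weak criterion with the
turn-flanking 8NH–5O medium-strong, (ii) the I′ template keeps 3NH–10O,
5NH–8O and 10NH–3O under the weak criterion, (iii) interior strand
residues stay in the β region, and (iv) the C6 contact of N-aminated
residues closes in the strand conformation. The same frozen template
serves every test and the acceptance script; it is never adjusted per
run. Because several cross-strand bonds sit intentionally close to the
weak-criterion boundary, torsion jitter reduces their per-frame detection
probability well below one — only at zero jitter do bond populations equal
state occupancies exactly, which is precisely what the zero-jitter
recovery tests exploit.

Gaussian jitter is applied to torsions, not Cartesian coordinates, so
chain geometry stays valid at any noise level; σ defaults to 10°.
Generation is a pure function of the `MarkovSpec` (states, row-stochastic
transition matrix, initial state, frame count, seed): the same seed gives
bit-identical ensembles.

What the generator does *not* emulate: physical sterics beyond build
geometry, side-chain packing, solvent, and kinetics calibrated to real
exchange rates. Passing recovery tests therefore demonstrates that the
analysis stack measures what was planted — not that real trajectories
would show these values.

## Numerical choices and problem sizes

* Strict `<`/`>` at all hydrogen-bond thresholds; exact boundaries absent.
* Clustering tie-breaks by lowest frame index; neighbour test strict.
* Circular means for angles; `wrapAngle` maps to (−180°, 180°].
* Degenerate inputs error early with the offending atom names (collinear
  dihedral triplets, collinear superposition selections, missing atoms,
  unresolvable NOE endpoints, non-stochastic transition matrices).
* Test problem sizes are chosen to exercise the statistics while keeping
  the default suite fast: 200-set builder round trips, 2000-frame
  ensembles for population recovery (99% binomial confidence intervals),
  100 random clustering instances of up to 60 frames against a
  brute-force oracle, and a 30-frame end-to-end determinism run. The
  acceptance script uses 1000-frame runs and clusters a 1-in-4
  subsample of the pooled trajectories.

## Known limitations

* Idealised geometry: fixed bond lengths/angles mean absolute hydrogen-bond
  geometries differ from force-field ensembles; populations near criterion
  boundaries are sensitive to jitter width.
* The shared strand template is a compromise between the I′ and II′
  hairpins; the I′ template's 12NH–1O terminal bond does not close (real
  hairpins relax their strands when the turn flips).
* Side chains are stubbed at CB, so restraints and bonds involving real
  side-chain atoms (e.g. aromatic or amide side-chain protons) are
  unsupported and flagged as unresolvable.
* The ψ-only turn classifier conflates extended backbones with II′; use
  the full classifier when unfolded states are present.
* The synthetic twist distribution is wide and its sign/magnitude are
  properties of the frozen template, not of any real peptide.
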