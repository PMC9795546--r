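# hairpintools

Conformational analysis of β-hairpin peptide ensembles, including peptides
with **backbone N-amination** (hydrazino acids, in which the amide H of a
residue is replaced by an NH₂ group).

β-hairpin model peptides — the 12-residue
H-Arg-Tyr-Val-Glu-Val-ᴅPro-Gly-Orn-Lys-Ile-Leu-Gln-NH₂ scaffold with its
ᴅ-Pro6–Gly7 turn is the canonical example — fold through a small set of
geometric signatures: cross-strand backbone hydrogen bonds (3NH–10O,
5NH–8O, 10NH–3O, 12NH–1O), a type I′ or II′ β-turn at the loop, and a
right-handed strand twist. N-amination rewires the donor inventory (the
NH₂ group donates through two hydrogens, NBHB1/NBHB2, and can close a weak
intraresidue **C6** ring on its own carbonyl, or reach the carbonyl of
residue i−2). This package provides the analysis machinery a structural
biologist needs to characterise such ensembles, plus a synthetic
conformer-ensemble generator with *planted* state structure so that every
statistic can be validated by parameter recovery.

## What it computes

| Quantity | Definition |
|---|---|
| Hydrogen-bond populations | geometric criteria; *medium-strong*: d(H···A) < 0.25 nm and ∠(D–H···A) > 135°; *weak*: d < 0.32 nm, ∠ > 90° (strict inequalities; angle at the hydrogen) |
| β-turn type | nearest canonical centre in wrapped (φ,ψ) space; I′ = (60°,30°)/(90°,0°), II′ = (60°,−120°)/(−80°,0°); or from ψ of the turn's i+1 residue alone |
| Peptide-plane flips | I′ ↔ II′ label transitions along the frame series |
| Hairpin twist | the 1C–12N–8C–5N cross-strand torsion, circular mean |
| Backbone RMSD | least-squares (Kabsch) superposition over backbone N/CA/C of residues 2–11 |
| Clustering | Daura greedy-medoid clustering at an RMSD cutoff (default 0.1 nm), multi-trajectory pooling with per-source contributions |
| NOE back-calculation | ⟨r⁻⁶⟩⁻¹/⁶ effective distances, pseudoatom corrections, violation report (threshold 0.05 nm) |
| Ramachandran occupancy | per-residue α/β/other fractions over declared rectangular regions |

The peptide chain builder constructs Cartesian coordinates from backbone
(φ, ψ, ω) with a fixed internal-geometry table (NeRF chain extension),
supports ᴅ-residues, the protonated N-terminus, the C-terminal amide, and
N-amination (NB trigonal on the backbone N, NH₂ plane oriented so the C6
contact can form in strand conformations).

## Worked example

```r
library(hairpintools)

top <- hairpinTopology(aminated = 9)       # Lys9 N-aminated variant
top
#> PeptideTopology: 12 residues, 75 atoms
#>   ARG-TYR-VAL-GLU-VAL-d-PRO-GLY-ORN-LYS*-ILE-LEU-GLN
#>   N-aminated sites (*): 9
#>   N-terminus: NH3+  C-terminus: amide

# a 500-frame synthetic trajectory: folded type II' hairpin vs unfolded,
# with dwell (sticky) kinetics and 8-degree torsion jitter
st  <- defaultStateTemplates(top, jitterSigma = 8)
P   <- matrix(c(0.95, 0.05, 0.15, 0.85), 2, 2, byrow = TRUE)
gen <- generateMarkovEnsemble(
  markovSpec(st[c("folded_II", "unfolded")], P, "folded_II",
             nFrames = 500, seed = 42), top)
ens <- gen$ensemble

# backbone RMSD against the folded template
ref <- buildConformer(top, hairpinTorsions(top, "II'"))
round(summary(rmsdSeries(ens, ref, backboneSelection(2:11))), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.025   0.078   0.126   0.235   0.391   0.884

# weak-criterion hydrogen bonds above 10% population
hb <- hbondPopulations(ens, criteria = hbondCriteria("weak"), minReport = 10)
head(hb[order(-hb$population), c("label", "population")], 5)
#>      label population
#>  9NBHB2-9O       89.8     <- intraresidue C6 bond of the aminated Lys9
#>     8NH-5O       72.4
#>  9NBHB1-7O       71.0     <- NH2(i) -> CO(i-2) bond
#>     5NH-8O       61.2
#>     8NH-6O       60.8

# turn typing and flips (psi-only classifier on d-Pro6)
su <- turnSummary(ens)
round(su$populationsByPsi, 1)
#>    I'   II' other
#>   6.6  93.4   0.0
round(twistSeries(ens)$mean)   # circular mean twist, degrees
#> [1] -30

# Daura clustering at 0.1 nm over the 2-11 backbone
head(clusterSizes(dauraCluster(ens, cutoff = 0.1)))
#> [1] 187  70  46  32  14   5

mean(gen$statePath == "folded_II")   # planted truth, for recovery checks
#> [1] 0.728
```

The RMSD distribution is bimodal (folded frames near 0.08 nm, unfolded
near 0.5 nm), the C6 bond of the aminated residue is the most populated
weak bond, and the ψ-based turn populations track the planted folded
fraction (the unfolded state's extended ψ also maps to II′, so the II′
population exceeds the folded occupancy — see the methods vignette).

A thin CLI over the same functions ships in
`inst/scripts/hairpin-analysis` (subcommands `synth`, `build`, `rmsd`,
`hbonds`, `turns`, `twist`, `cluster`, `noe`, `run`); `run` drives the
whole pipeline from a YAML config (see `inst/extdata/example_run.yaml`)
and writes TSV/JSON reports whose headers record the package version,
config hash and seed.

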