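---
title: "Methods: segment-wise conformational analysis of gamma-tubulin complexes"
author: "TuSCmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-wise conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TuSCmorph)
```

## The model and its assumptions

γ-tubulin complexes act as structural templates for microtubule
nucleation, and the analysis questions this package answers are
geometric: how far apart are homologous rigid segments in two
conformations of a complex, which direction do the γ-tubulins move
during activation, is a tubulin subunit straight or curved, and what is
the physicochemical character of a subunit interface.

The central assumption throughout is **segment rigidity**: GRIP1 and
GRIP2 domains of the Spc/GCP proteins and each γ-tubulin copy are
treated as rigid bodies. This mirrors how inter-domain rearrangements
are analysed in the field — displacement is attributed to the hinges
between segments, not to internal deformation. When a segment is not in
fact rigid, the per-segment RMSD absorbs the internal deformation;
nothing in the procedure detects or corrects it.

### The morph-compare procedure

Given a query model $Q$ and a reference model $R$ split into homologous
segments $s = 1..k$:

1. for each segment, build a residue correspondence (global sequence
   alignment, BLOSUM62, affine gaps 10/1), collect paired Cα atoms and
   compute the least-squares rigid superposition of the query segment
   onto the reference segment (Kabsch, SVD with reflection correction);
   place a copy of the query segment with that transform;
2. assemble the placed copies into a composite model — the query drawn
   in the reference conformation;
3. superpose the composite back onto the original query using only the
   union of the *anchor* segments (one whole spoke). This fixes the
   frame: all displacements are expressed relative to the anchor spoke;
4. report per-segment RMSD between composite and query, per-residue
   displacement vectors, their per-segment mean arrows, and the change
   in the inter-γ-tubulin centroid distance.

Anchor-segment RMSD after step 3 is the residual anchor misfit: zero
when the anchor spoke is internally rigid between the conformations, and
a useful diagnostic otherwise. For a rigid tilt of one block the
reported RMSD has the closed form
$\sqrt{\tfrac1n\sum_i |(\mathbf{R}-\mathbf{I})(x_i - h)|^2}$
(rotation $\mathbf{R}$ about hinge $h$); the synthetic generator returns
exactly this value as ground truth, and the tests require agreement to
1e-6 Å.

### Tubulin conformation calls

A subunit is classified by docking *complete* straight and curved
reference tubulin models into the subunit's density segment (rigid-body
fit started from the sequence-matched superposition onto the subunit
model) and scoring helices α6/α7 two ways: Cα RMSD against the subunit
model in the docked positions (no re-superposition — re-fitting the
helices would erase precisely the signal of interest), and about-mean
cross-correlation between simulated density of the docked helices and
the experimental map within 3 Å of the docked helix atoms. The label is
`straight` only if the straight reference wins on *both* criteria,
`curved` only if it loses both, otherwise `indeterminate` — ties are
never broken, because a call that the two criteria do not support
consistently is not a call. The rule is enforced by the validity method
of `ConformationCall` and tested by truth-table enumeration.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| atom subset | `CA_ONLY` | — | Cα is the stricter of the two common backbone conventions for segment RMSD; `BACKBONE` (N, CA, C, O) and `ALL_HEAVY` are options. |
| matchmake-style pruning | off | — | post-fit pruning (drop pairs > 2.0 Å, refit once) is offered only to probe sensitivity; interactive tools differ in their defaults, so the reproducible default is no pruning. |
| `sigmaFactor` | $1/(\pi\sqrt2) \approx 0.225$ | — | the common Gaussian-resolution convention of interactive map simulation (`simulateDensity`); σ = sigmaFactor × resolution. |
| simulation padding | 3σ | Å | covers > 99.7% of each Gaussian; mass-conservation tests use 4σ. |
| zone radius | 2.5 | Å | ligand-site zone masking radius. |
| ligand ratio threshold | 0.5 | — | γ-site/rest mean-density ratio below which a site is called "GDP-like". |
| contact cutoff | 4.5 | Å | common heavy-atom contact convention (inclusive). |
| salt-bridge cutoff | 4.0 | Å | Asp/Glu side-chain O — Lys/Arg/His side-chain N. |
| hydrophobic residue | Kyte–Doolittle > 0 | — | A, C, F, I, L, M, V; the table is exported (`kdHydropathy`) and overridable. |

**Segment boundaries are configuration, not defaults.** GRIP1/GRIP2
domain boundaries are not printed in the primary literature and differ
between depositions, so the package refuses to guess: segment ranges
come from a YAML config (`readSegmentConfig()`), and the shipped example
(`inst/extdata/segments_gtusc_example.yaml`) marks its boundaries as
placeholders to edit. Likewise, which accession is the "straight" and
which the "curved" tubulin reference is a user label, not hard-coded,
and helix α6/α7 ranges follow each structure's own numbering.

## Numerical choices

- **Kabsch degeneracy.** Fewer than 3 pairs, or a mobile point cloud of
  rank < 2 (collinear), is an error rather than a silently unstable fit.
  Reflections are corrected by flipping the sign of the smallest
  singular vector.
- **Residue identity.** Author numbering from the file, with insertion
  codes, is the identity everywhere; nothing is ever re-indexed, so
  reported residues can be cross-checked against depositions directly.
  Altlocs resolve to the highest-occupancy conformer (ties: first altloc
  id alphabetically). Waters and HETATM records are excluded from all
  superposition selections.
- **Alignment tie-breaking** follows the deterministic dynamic-program
  order of the underlying aligner; for the identical or near-identical
  sequences of homologous segments the pairing is unambiguous anyway.
- **Grids.** A map is values on a regular grid with
  world = origin + index × voxel. Simulation enforces
  resolution ≥ 2 × voxel (sampling guard). Map values are read by
  trilinear interpolation; points outside the grid contribute the
  configurable `outside` value (0 for fitting).
- **Rigid-body fitting** maximizes the mean interpolated map value at
  the atom positions over 6 degrees of freedom. Because a map simulated
  at 3.6 Å resolution has σ ≈ 0.81 Å, the score landscape is sharp; the
  search is therefore coarse-to-fine (Gaussian-smoothed copies of the
  map at 6, 3, 1.5, 0 Å extra width) with Nelder-Mead restarts until the
  placement moves < 0.01 Å and < 0.01°, then a fine polish with a
  shrunk simplex. The optimizer is strictly local by design — matching
  interactive fitting practice — and global search is out of scope.
  Trilinear interpolation biases the discrete optimum by a sub-voxel
  amount; on a 0.9 Å grid this bias is well below the 0.1 Å / 0.5°
  recovery tolerance the tests enforce, which is why fit-accuracy checks
  simulate their maps at that grid.
- **Centroids** are unweighted Cα centroids ("centers" in the loose
  sense used in the field); an occupancy-weighted all-atom option
  exists. A centroid-distance change below 0.05 Å is reported as
  `unchanged`.
- **Degenerate inputs** have defined behaviour: empty atom lists leave a
  remove-mode zone mask unchanged and empty a keep-mode mask; a
  zero-density map makes the ligand-site ratio `indeterminate`; zero
  variance under about-mean correlation is an error.

## The synthetic generator

`makeToyPair()` builds a two-spoke Y-shaped assembly — three rigid
blocks per spoke (GRIP1, GRIP2, γ-body), each a bundle of ideal
poly-alanine Cα helices (rise 1.5 Å, 100° twist, 2.3 Å radius) — and a
"closed" state in which the spoke-2 GRIP2 + γ block is tilted by a
configurable angle (default 15°, the scale of a template-closure motion)
about the spoke-2 inter-domain hinge. Optional seeded Gaussian noise is
added to the closed-state coordinates; `makeToyMap()` adds seeded voxel
noise to simulated maps. Every output is a pure function of the
parameters including the seed.

What it emulates: the segment-rigid architecture, a known inter-segment
hinge motion with analytic per-residue displacements, homologous
sequences (identical by construction; `mutateResidues()` decorates them
for alignment tests), and maps with controlled SNR.

What it does not emulate: side chains and real secondary-structure
packing, non-rigid segment deformation, resolution anisotropy and
B-factor falloff in experimental maps, and real domain boundaries.
Passing tests therefore demonstrate the correctness of the machinery —
superposition, assembly, re-anchoring, displacement algebra, density
scoring — not the biological adequacy of any particular segmentation of
a real deposition, which remains the user's modelling decision.

For the noisy-recovery checks the expected segment RMSD is inflated by
first-order error propagation of the two estimated transforms:
$\sqrt{r_0^2 + 6\sigma^2/n_{seg} + 6\sigma^2/n_{anchor}}$ (6 parameters
per fit), and the Monte-Carlo mean over 20 seeds must fall within 3
standard errors.

## Problem sizes

The default toy assembly is 6 segments × 60 Cα (360 atoms); simulation
grids are 1.0–1.2 Å voxels (a few 10^4 voxels), 0.9 Å where fit accuracy
is measured; noisy recovery uses 20 seeds and correlation checks 10.
These sizes make every property exact or statistically sharp while the
whole suite runs in about a minute and a half.

## Known limitations

- The comparison of deposited models stands or falls with the
  user-supplied segment boundaries and spoke/chain assignments; there is
  no automatic domain or spoke detection.
- Rigid-body fitting is local; a start placement more than a few
  Ångström or tens of degrees from the basin of the correct pose will
  converge elsewhere. Starts are therefore derived from sequence-matched
  superpositions.
- Interface characterization reports contacts, hydrophobic fractions and
  salt bridges; it deliberately computes no buried surface area or
  interaction energies.
- mmCIF is read but not written; written models are PDB, with that
  format's 1e-3 Å coordinate precision.
- The cross-correlation convention (about-mean, 3 Å mask around the
  fitted atoms) is one of several used by interactive tools; when
  reproducing published correlation values both about-mean and about-zero
  variants should be computed (`aboutMean` flag) and compared within a
  tolerance that absorbs the convention.
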