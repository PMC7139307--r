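---
title: "Stability metrics for cross-beta fibril trajectories: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability metrics for cross-beta fibril trajectories: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilstab)
```

## The problem

Amyloid-beta 42 (Abeta42) fibrils — in particular the S-shaped polymorph, in
which each 32-residue chain (Abeta residues 11–42) folds into a triple-strand
meander and chains stack along the fibril axis at a ~0.48 nm rise — are a
primary structural target for small molecules intended to destabilize toxic
aggregates. Molecular-dynamics studies of fibril–ligand complexes typically
quantify a compound's effect with three trajectory-level indicators computed
over a late analysis window:

1. **beta-sheet content**: the fraction of residues assigned to beta
   structure per frame;
2. a **chain-orientation order parameter** measuring how well each chain
   keeps its starting internal orientation;
3. the **inter-chain interaction area** between adjacent stacked chains,
   whose collapse signals chain detachment;

plus a **per-residue ligand contact probability map**, and, upstream of
docking, **receptor selection** as the centroid of the most populated RMSD
cluster of an apo trajectory. `fibrilstab` implements this analysis layer as
a tested, deterministic pipeline with a synthetic trajectory generator, so
every stage can be validated without an MD engine.

## Models and procedures

### Beta assignment (Kabsch–Sander subset)

Hydrogen bonds are scored with the DSSP electrostatic approximation

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \;\text{kcal/mol},$$

distances in Ångström (the one place the package works in Å internally; all
interfaces are nm). A bond exists when $E < -0.5$ kcal/mol; any of the four
distances under 0.5 Å clamps the energy to $-9.9$ (clash rule); per donor at
most the two best-energy acceptors are kept (no-bifurcation rule); residues
closer than two positions in sequence are excluded. Amide hydrogens, absent
from typical MD PDB exports, are placed 0.10 nm from N along the previous
residue's C→(anti-O) direction; chain-first residues and prolines get none.
Parallel and antiparallel bridges follow the standard bridge rules (with
hb(i, j) meaning "CO of i accepts the NH of j"), bridges chain into ladders,
residues in ladders of length ≥ 2 are `E`, isolated bridges `B`, everything
else `C` — the package deliberately implements only the beta classes, since
only beta content enters the stability report. Both `E`-only and `E+B`
counting are exposed; the default counts both, which is the DSSP "beta
structure" reading; for the idealized fixtures the two differ negligibly.
A 9 Å Cα–Cα prefilter (the DSSP convention) bounds the energy search.

### Order parameter

For chain $c$ and residue $n$, let $\vec v_{c,n}(t)$ be the **unit** vector
from the chain's Cα centroid to residue $n$'s Cα at frame $t$. The order
parameter of frame $t$ is

$$\mathrm{ordP}(t) = \frac{1}{N_c N_r} \sum_{c=1}^{N_c} \sum_{n=1}^{N_r}
\vec v_{c,n}(0) \cdot \vec v_{c,n}(t),$$

averaged over the analysis window. Values near 1 mean the starting
orientation is preserved; disorder drives the mean dot product toward 0.
Two readings of this statistic are defensible and both are implemented:

* **Normalization.** A dot product of raw connecting vectors has units of
  nm² and "close to 1" would be meaningless; vectors are therefore
  normalized before the product. This is the only reading under which 1 is
  exactly "perfect alignment".
* **Centre granularity.** The default pairs each residue's Cα with its
  *chain's* centroid (a fan of chain-frame orientation vectors, the reading
  consistent with chain-order statistics used for fibrils); the alternative
  — each Cα against its own residue's heavy-atom centre — is available as
  `com_mode = "residue"`.
* **Fitting.** Frames are least-squares fitted (Kabsch, Cα, all chains)
  onto the reference before measuring, because a fibril tumbling in the box
  would otherwise degrade ordP for every system alike; `fit = FALSE` gives
  the literal body-frame reading. With chain-centroid vectors the statistic
  is already translation-invariant; fitting additionally removes global
  rotation.

### Interaction area

The primary metric is buried solvent-accessible surface area per adjacent
chain pair in stacking order: $\tfrac12[S(A) + S(B) - S(A \cup B)]$, with
SASA from a Shrake–Rupley quadrature (deterministic Fibonacci sphere,
default 960 points/atom, probe 0.14 nm, vdW radii C 0.17, N 0.155, O 0.152,
S 0.18, H 0.12 nm). "Contact surface with a 0.35 nm cutoff" can also be
read as a count-based metric, so the series additionally reports the number
of cross-chain heavy-atom pairs within the cutoff per frame; both columns
are emitted and neither is asserted to be the other. Buried area is clamped
at 0 (quadrature noise can dip marginally negative for separated chains,
which triggers a warning only beyond 1e-6 nm²).

### Contact probability and bound-frame masking

A residue *identity* (number + name, chain-agnostic) is in contact in a
frame when any chain's copy has a heavy atom strictly within 0.35 nm of a
ligand heavy atom; the probability is contact frames over considered
frames. Chains are pooled because the fibril is a stack of identical
chains, so only the residue type is informative. A ligand that detaches
during a run would dilute its own map, so estimation is restricted to
frames where the minimum ligand–receptor distance is below the same cutoff
(strictly: a frame exactly at the cutoff is unbound).

### Receptor selection

Frames of the clustering window (default the last 50 ns) are clustered by
single-linkage connected components of the pairwise Cα RMSD matrix at a
0.1 nm cutoff — the `linkage` semantics of the GROMACS clustering tool,
including the strict `<` comparison (exposed as `strict = FALSE` for the
non-strict reading, since the convention is not universal). The centroid —
the member with minimum mean RMSD to the rest of the most populated
cluster, ties to the lowest frame index — is written out as the docking
receptor. Whether clustering should fit on Cα or all heavy atoms is
likewise not universal; Cα is the default and the mask is a parameter.

## The synthetic generator

`build_ideal_fibril()` constructs an idealized cross-beta stack: each chain
is a planar three-strand meander (segments 11/10/11 residues, Cα step
0.38 nm, strand separation 0.6 nm), chains are exact z-translates at a
0.48 nm rise, carrying the true Abeta 11–42 residue names. Backbone N and C
sit 0.19 nm before and after each Cα along the strand — slightly longer
than physical bond lengths, a deliberate idealization — and carbonyl
directions alternate up/down along the chain (the pleat). This phasing
makes the Kabsch–Sander machinery find inter-chain bonds at every
in-register residue (donor geometry gives E ≈ −1.5 kcal/mol at the default
rise) and hence parallel ladders, so the ideal pentamer scores > 80% `E`
with turn and edge residues `C`. The builder is calibration-tested against
the energy threshold in the suite.

`plant_ligand()` adds a rigid 20-atom carbon blob at a named site (pocket
centre of the middle chain's meander, midpoint between two middle chains,
or beyond the terminal chain); `make_trajectory()` produces seeded,
bit-reproducible regimes:

| mode | model | default amplitude |
|---|---|---|
| `stable` | i.i.d. Gaussian jitter on all atoms | 0.01 nm sd |
| `melt` | jitter sd ramping linearly 0 → amplitude | 0.2 nm |
| `detach` | terminal chain slides along +x after onset (plus 0.01 nm baseline jitter) | 10 nm final |
| `pocket_distort` | pocket strand (residues 22–31) displaced in-plane after onset | 0.5 nm |
| `scramble` | each chain uniformly randomly rotated about its centre, every frame | — |

The detach displacement must exceed the ~3.8 nm chain extent for the
terminal interface to vanish; 10 nm (~2.5× the chain) guarantees complete
separation over the final quarter of the run. Defaults mirror the
conditions of long fibril MD studies: 150 frames at 1 ns/frame, stability
metrics on the last 25 ns, clustering on the last 50 ns.

**What the generator does not emulate**: side chains, physical force
fields, solvent, realistic fluctuation spectra, or gradual cooperative
unfolding. Passing tests on these fixtures demonstrate that the *metrics
and pipeline* are computed correctly and respond to planted structural
signals with the expected sign and approximate magnitude — not that real
MD trajectories of real fibrils would reproduce any particular published
value. Headline numbers from nanosecond-scale atomistic studies (e.g. a
wild-type beta content near 38%) require real solvated MD of the NMR
structure and are out of reach of a synthetic backbone model; the package
makes no claim to reproduce them.

## Numerical choices

* All coordinates are nm; PDB I/O converts Å at the boundary (3-decimal PDB
  fields make round-trips exact to 1e-4 nm). Kabsch–Sander energies convert
  to Å inside the operator only.
* The Kabsch solution enforces a proper rotation by sign-flipping the
  smallest singular vector pair; references with rank < 2 (collinear) are
  rejected. Weights default to uniform — mass-weighting is deliberately not
  applied anywhere.
* Strict `<` at every cutoff (contact, bound-frame, cluster), documented
  per function; boundary frames and boundary RMSD pairs are excluded.
* Cluster ids are ordered by decreasing size with ties by lowest member
  frame; centroid ties also resolve to the lowest frame. Results are
  invariant under frame relabeling up to these rules.
* "Last W ns" resolves to the final `round(W / time_per_frame)` frames; a
  window longer than the trajectory is an error, never silently truncated.
* Random stages (ligand jitter, trajectory noise) run under a locally
  scoped RNG seeded from the caller, leaving the session RNG untouched; a
  given seed reproduces coordinates to the last bit.

## Problem sizes

The test-suite fixtures use 2–3 chains of 12 residues where the full
pentamer is not needed, 240–480 SASA points where 1% quadrature accuracy
suffices (convergence of the quadrature itself is tested separately), and
60-frame runs with 5 seeds per regime for the separation checks. The
acceptance script analyzes full-default systems: the 5 × 32-residue
pentamer, 150-frame trajectories, 960-point SASA, windows of 25/50 ns.

## Known limitations

* Only beta classes are assigned; helix/turn analysis is out of scope.
* SASA is quadrature-based (no analytic Lee–Richards surface); accuracy is
  bounded by the point count, which is why symmetric quantities are
  computed from the same point set (buried area is exactly symmetric).
* No periodic-boundary imaging: trajectories are assumed whole-molecule
  and unwrapped, as standard MD post-processing produces.
* The PDB reader supports the fixed-column ATOM/HETATM dialect with
  MODEL/ENDMDL frames; mmCIF and binary trajectory formats are out of
  scope.
* Beta content is not a monotone readout of every distortion: the
  in-plane `pocket_distort` displacement can transiently bring backbone
  strands into new alignments and slightly *raise* the assigned beta
  fraction. The discriminating signals for that regime are the
  interaction area, the order parameter and the contact map, not beta
  content — which is exactly why the report carries all three metrics.
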