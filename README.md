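# fibrilstab

Stability metrics and docking-receptor selection for trajectories of
stacked cross-beta amyloid fibrils, such as the S-shaped Aβ42 polymorph
(five chains of residues 11–42 stacked at a ~0.48 nm rise).

Small molecules that bind amyloid fibrils are commonly classified by what
they do to the fibril's ordered structure over a molecular-dynamics run:
some wedge between chains and detach them, some distort the binding pocket,
some stabilize it. `fibrilstab` implements the trajectory-analysis layer
that makes this classification quantitative, for structural
bioinformaticians working on fibril–ligand systems:

* **Beta-sheet content** per frame, from a Kabsch–Sander hydrogen-bond
  model (energy `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
  kcal/mol, bond when `E < −0.5`) with the standard bridge/ladder rules
  restricted to the beta classes E/B.
* A **chain-orientation order parameter**
  `ordP(t) = mean over chains c, residues n of v̂_cn(0) · v̂_cn(t)`,
  where `v̂_cn` is the unit vector from chain *c*'s Cα centroid to residue
  *n*'s Cα; 1 means the starting orientation is preserved.
* **Inter-chain interaction area**: buried Shrake–Rupley SASA
  `½[S(A) + S(B) − S(A∪B)]` summed over adjacent chain pairs, plus a
  count-based contact metric at a 0.35 nm cutoff.
* **Per-residue ligand contact probability**, chain-aggregated, restricted
  to frames where the ligand is actually bound (minimum ligand–receptor
  distance < 0.35 nm).
* **Receptor selection**: single-linkage clustering of the pairwise Cα
  RMSD matrix at a 0.1 nm cutoff; the most populated cluster's centroid
  (minimum mean RMSD member) becomes the ensemble-docking receptor.
* A **synthetic generator** of idealized cross-beta pentamers,
  pseudo-ligands and seeded distortion regimes (stable / melt / detach /
  pocket-distort / scramble), so the whole pipeline is testable and
  demonstrable without an MD engine.

Everything is tibble-first and pipe-friendly; fitted result objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Build the ideal pentamer, dock a pseudo-ligand in the S-shape pocket, let
the fibril "melt", and summarize the last 25 ns:

```r
library(fibrilstab)

fib <- build_ideal_fibril()
fib
#> <fibril_structure> 640 atoms, 5 chain(s) [ABCDE], 640 protein / 0 hetero atoms

complex <- plant_ligand(fib, site = "pocket", seed = 1)
traj <- make_trajectory(complex, mode = "melt", n_frames = 150, seed = 1)
report <- summarize_complex(traj, config = analysis_config(seed = 1))
report
#> <stability_report> last 25 ns (25 frames)
#>   beta content     : 11.3% +/- 3.6%
#>   order parameter  : 0.936
#>   inter-chain area : 54.97 +/- 2.16 nm^2
#>   ligand           : bound in 25/25 window frames
```

The melting regime has destroyed most of the hydrogen-bond registry (the
intact fibril assigns > 80% beta), and the order parameter has dropped
below 1; a `stable` run of the same system stays near 87% beta and
ordP ≈ 0.999. The contact map shows the ligand pinned in the pocket
strand:

```r
report$contact_map |> dplyr::arrange(dplyr::desc(probability)) |> head(5)
#> # A tibble: 5 × 3
#>   resid resname probability
#>   <int> <chr>         <dbl>
#> 1    17 LEU               1
#> 2    25 GLY               1
#> 3    26 SER               1
#> 4    27 ASN               1
#> 5    28 LYS               1
```

Receptor selection on an apo run (last 50 ns, 0.1 nm cutoff):

```r
apo <- make_trajectory(fib, "stable", n_frames = 150, seed = 1)
m <- pairwise_rmsd_matrix(apo, frames = 101:150)
linkage_cluster(m, cutoff = 0.1)
#> <cluster_result> 50 frames, 1 cluster(s) at cutoff 0.1 nm; centroid frame 106
#>   (cluster of 50 frames)
```

`run_cluster()`, `run_analyze()` and `run_demo()` orchestrate these stages
with CSV/PDB outputs whose headers record the exact configuration;
`inst/scripts/fibril-tools.R` wraps them for the shell
(`synth` / `cluster` / `analyze` / `demo` subcommands).

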