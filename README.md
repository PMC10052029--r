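# kindyn

Comparative molecular-dynamics trajectory analysis for kinase
conformational selectivity, in R.

## The problem

Selective kinase inhibition often hinges not on which residues line the
ATP pocket but on which *conformations* the receptor can reach: an
inhibitor that drives the glycine-rich phosphate-binding loop (P-loop)
from its open to its closed conformation gains a hydrophobic enclosure —
and selectivity — that a static structure comparison cannot explain.
Interrogating that mechanism from MD trajectories requires a battery of
coordinated analyses, each individually standard but rarely available as
one tested, reusable pipeline. `kindyn` provides that pipeline for anyone
comparing two simulated ensembles (apo vs. holo, or two isoforms bound to
the same ligand):

* **Stability** — Kabsch superposition, per-frame RMSD with independent
  fit/report selections, per-residue RMSF about the iterated mean
  structure.
* **Correlated motions** — the dynamic cross-correlation matrix
  `C_ij = <Δr_i·Δr_j> / (<Δr_i²><Δr_j²>)^(1/2)` over alpha-carbons, with
  the conventional `|C| < 0.3` display mask and region-block summaries.
* **Collective motions** — PCA of RMS-fitted coordinates, porcupine
  fields, and free-energy landscapes `G_i = −k_B T ln(N_i/N_max)` over any
  two reaction coordinates.
* **Kinetics** — Markov state models: k-means microstates (k-means++
  seeding), reversible transition-matrix estimation, implied timescales
  `t_i = −τ/ln|λ_i|`, Chapman–Kolmogorov validation, PCCA+ metastable
  coarse-graining, mean first passage times, representative
  conformations.
* **Energetics** — MM/GBSA combination
  `ΔG = ΔE_internal + ΔE_elec + ΔE_vdW + ΔG_pol + ΔG_np` (entropy
  omitted), per-residue decomposition with a two-sided 1 kcal/mol
  significance threshold, geometric hydrogen-bond occupancy.
* **Community networks** — residue graphs from 4.5 Å / 75%-occupancy
  heavy-atom contacts, edge distances `d_ij = −ln|C_ij|`, Girvan–Newman
  communities (own weighted-betweenness implementation, cross-checked
  against brute force and igraph), betweenness-weighted intercommunity
  pathway strengths.

Because real microsecond trajectories are rarely shippable, the package
also contains first-class synthetic generators with planted ground truth —
metastable Brownian dynamics on a multi-well potential, a two-lobe loop
pseudo-protein, block-structured displacement covariances, Markov chains,
additive energy tables — so every estimator is tested against values known
by construction. See `vignettes/methods.Rmd` for the models, assumptions
and numerical choices.

## Worked example

Two synthetic 50-residue systems share one seed; in the second the ligand
locks the loop in the closed basin:

```r
library(kindyn)

cfg_apo  <- run_config(seed = 7, synthetic = list(closed = FALSE, n_frames = 250),
                       msm = list(k = 20, lag = 2, n_metastates = 2))
cfg_holo <- run_config(seed = 7, synthetic = list(closed = TRUE,  n_frames = 250),
                       msm = list(k = 20, lag = 2, n_metastates = 2))
apo  <- run_pipeline(cfg_apo)
holo <- run_pipeline(cfg_holo)
compare_systems(apo, holo)
```

which prints

```
  d_rmsd_mean              -0.01686
  d_loop_rmsf_mean         -0.3795
  d_loop_hinge_correlation -0.003966
  d_loop_ligand_distance   -3.162
  d_dG_binding             -6.186
  d_n_communities          1
  d_n_pathways             0
  loop_hinge_edge          FALSE  TRUE
```

Deltas are holo minus apo. The bound system's loop sits 3.2 Å closer to
the ligand, fluctuates 0.38 Å less (it is locked in its basin), its
interaction energy is 6.2 kcal/mol more favourable, and a loop-to-hinge
contact edge appears in the residue network only when the loop closes —
the network-level signature of the closed conformation. Each
`run_pipeline()` call also writes `rmsd.tsv`, `rmsf.tsv`, `dccm.tsv`,
`pca_projections.tsv`, `msm.json`, `per_residue_energy.tsv`,
`network.json`, `summary.json` and a parameter log into its output
directory.

The energy bookkeeping is exact by construction; combining component
tables planted with the published means for an FGFR1–inhibitor complex:

```r
d <- c(E_internal = 0, E_elec = -47.72, E_vdw = -18.60, G_pol = 41.28, G_np = -5.82)
tabs <- make_energy_tables(list(complex = d, receptor = d * 0, ligand = d * 0),
                           list(complex = d * 0, receptor = d * 0, ligand = d * 0),
                           n_frames = 5, seed = 1)
mmgbsa_combine(tabs$complex, tabs$receptor, tabs$ligand)
#> <binding_energy> dG_binding = -30.86 +/- 0.00 kcal/mol over 5 frames
```

A thin shell entry point (`inst/scripts/mdselect run|compare`) wraps
`run_pipeline()`/`compare_systems()` for YAML-configured runs.

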