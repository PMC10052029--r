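---
title: "Methods: comparative trajectory analysis of kinase conformational selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative trajectory analysis of kinase conformational selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindyn)
```

# Scope and data model

`kindyn` analyses molecular-dynamics trajectories of kinase systems with the
goal of *comparing* two ensembles — typically a ligand-free (apo) against a
ligand-bound (holo) system, or two receptor isoforms bound to the same
inhibitor — through six coordinated stages: structural stability (RMSD/RMSF),
residue motion cross-correlation, principal component analysis with
free-energy landscapes, Markov state model kinetics, MM/GBSA energy
bookkeeping, and residue community networks. The central biological
observable this design serves is the open-to-closed transition of a mobile
loop (such as the glycine-rich phosphate-binding loop that caps a kinase's
ATP site) and the signature that transition leaves in each analysis surface.

All stages operate on three small data types. A **topology** names atoms and
groups them into residues (integer residue ids, chain ids, a ligand flag); a
**trajectory** holds a `frames x atoms x 3` array of Cartesian coordinates in
Angstrom; a **selection** is an ordered set of atom indices produced by a
small grammar (`"resid 487-494 and name CA"`, `backbone`, `heavy`, `ligand`,
unions with `or`). Multi-model PDB is the interchange format (one `MODEL`
block per frame, `%8.3f` coordinates, so round trips are exact to the
format's three decimals); a plain TSV coordinate table is the alternative.
Atoms are indexed 1-based internally, following the language convention;
every user-facing report speaks in residue ids, never internal indices.
Alternate locations other than blank/'A' are dropped and insertion codes are
appended to the residue label, which makes parsing of real PDB files
deterministic without modelling crystallographic ambiguity.

Units are kcal/mol, Angstrom, Kelvin and picoseconds throughout, with the
Boltzmann constant `kB = 0.0019872041` kcal/(mol K) and the Coulomb factor
`332.0636` kcal A/(mol e^2).

# Stability metrics

Superposition uses the Kabsch algorithm: the SVD of the weighted
cross-covariance matrix with the usual determinant correction, so a proper
rotation (never a reflection) is returned even for degenerate (collinear)
point sets, where the SVD's deterministic ordering breaks the tie. RMSD
series fit each frame on one selection and report on another — fitting on
the rigid scaffold while reporting on the mobile loop is how loop deviation
is isolated.

RMSF uses the iterated mean-structure reference: frames are superposed onto
their mean, the mean is recomputed, and the loop repeats until the mean
moves less than 1e-6 A (typically 2-4 iterations). This is the standard
fluctuation definition; fitting to frame 1 instead would mix the reference's
own offset into every fluctuation. Equilibrated RMSD summaries (mean ±
sample SD) default to the second half of each series; the window is a
configuration parameter because published reports rarely state theirs.
Replicas are analysed independently and pooled by concatenation (RMSD) or
element-wise averaging (correlation matrices), both configurable.

# Cross-correlation of residue motions

The dynamic cross-correlation matrix over alpha-carbons is
`C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with displacements taken
about the time mean after the same iterated superposition as RMSF. Values
near +1 mark concerted motion, near -1 anti-correlated motion. A residue
with zero fluctuation cannot be normalised; its off-diagonal entries are set
to 0 with a warning rather than propagating NaN. For display, entries with
`|C| < 0.3` are conventionally masked; the masked sentinel is `NA`, not 0,
so downstream network code can distinguish "weakly correlated" from "no
estimate". Region summaries (mean, mean |C|, fraction positive over a block)
quantify statements like "the loop moves with the hinge".

# Collective motions and free-energy landscapes

PCA is performed on the flattened coordinates of a selection after RMS
fitting every frame to the *same* reference structure — fitting each frame
to its predecessor or to a moving mean would leak rigid-body motion into the
modes. Eigenvector signs are fixed by making the largest-magnitude component
positive so porcupine plots (per-atom arrows scaled by the root eigenvalue)
are reproducible; the overall sign of an eigenvector is otherwise arbitrary
and flipping it flips every arrow.

Free-energy landscapes Boltzmann-invert a 2-D histogram:
`G_i = -kB T ln(N_i / N_max)` (so the most populated bin is exactly 0 and a
bin with 1/e of its population sits `kB T = 0.596` kcal/mol higher at
300 K). Empty bins are undefined (`NA`), never a number. The default grid is
100 x 100 bins over the data's bounding box padded by 1%; any pair of
reaction coordinates works (PC1/PC2, or loop RMSD against loop-ligand
distance). The loop-ligand distance defaults to center-of-geometry to
center-of-geometry, with minimum inter-atomic distance behind a flag, since
published landscape axes rarely say which variant they used.

# Markov state models

Frames projected onto the leading principal components are discretised by
k-means (k-means++ seeding under an explicit seed, Lloyd refinement; the
conventional setting for this kind of analysis is 100 centers and 100
iterations, both configurable). Transition counts use a sliding window at
lag `tau` and never cross replica boundaries. States outside the largest
mutually connected set are trimmed before row normalisation. The default
estimator symmetrises counts, `(C + C')/2`, which enforces detailed balance
by construction; the raw estimator is kept for oracle tests against planted
chains.

Validation follows standard practice. Implied timescales are
`t_i = -tau / ln|lambda_i(tau)|`; lag-independence evidences Markovianity.
(The alternative form without the division that sometimes appears in print
is dimensionally inconsistent — a timescale must carry time units — so the
standard definition is used.) The Chapman-Kolmogorov test coarse-grains
microstates to metastates, propagates the base-lag matrix `T(tau)^n` and
compares its metastate self-transition probabilities against matrices
estimated directly at `n tau`; Markovian data keeps the maximum deviation
within sampling error while lumping kinetically distinct states produces a
clear violation.

Coarse-graining uses a PCCA+-style scheme: the dominant eigenvectors of the
reversible transition matrix (computed via the symmetrised
`D^1/2 T D^-1/2` form for numerical stability) span a simplex whose
vertices are located by greedy deflation — repeatedly selecting the
microstate row most distant from the span of previously chosen vertices —
and memberships are the barycentric coordinates, clipped to `[0, 1]` and
renormalised. Mean first passage times solve the absorbing linear system
`m = 1 + T[ns, ns] m` over non-sink states and report the
stationary-weighted mean over the source set, in lag steps, frames and
physical time. Representative conformations minimise the distance to each
metastate's occupancy-weighted centroid in projection space, with ties
broken by the lowest frame index; a similarity-score definition for this
choice is not standardised in the literature, and centroid proximity is this
package's documented convention.

# MM/GBSA bookkeeping

The binding free-energy stage consumes per-frame additive component tables
(`E_internal`, `E_elec`, `E_vdw`, `G_pol`, `G_np`) for complex, receptor and
ligand and combines them as `dX = X_complex - X_receptor - X_ligand`,
reporting per-component means ± SD and their sum as the total. The solute
entropy term is omitted, the usual end-point practice when comparing
structurally similar complexes whose entropic contributions largely cancel.
The package deliberately does **not** implement a Generalized-Born solver:
polar solvation is consumed as data (from engine output files or the
synthetic generator), because the scientific content here is the
combination, conservation (total = sum of component means, always) and
decomposition bookkeeping, not a re-derivation of continuum electrostatics.
Under the single-trajectory convention all three tables derive from the same
frames and the internal term cancels exactly.

Per-residue decomposition averages a per-frame residue-to-ligand interaction
table and flags residues whose mean contribution exceeds 1 kcal/mol *in
magnitude* — two-sided, because a strongly unfavourable residue is as
mechanistically informative as a favourable one. A toy pairwise evaluator
(Coulomb + Lennard-Jones + a per-contact nonpolar term, 12 A cutoff) exists
solely to produce such tables for synthetic systems; it is documented as a
toy, not a force field. Hydrogen-bond occupancy uses the common geometric
criterion (donor-acceptor distance <= 3.5 A; donor-H-acceptor angle >= 120
degrees when hydrogens exist, distance-only otherwise), since published
occupancy tables rarely state their criterion.

# Residue community networks

Nodes are residues (their alpha-carbons); an edge exists when the *minimum
heavy-atom distance* between two residues is within 4.5 A for at least 75%
of frames. The heavy-atom convention matters: 4.5 A is far below typical
alpha-carbon/alpha-carbon contact distances, so a literal alpha-carbon
cutoff at that radius would produce an almost empty graph — the standard
dynamical-network convention (heavy-atom contacts between alpha-carbon
nodes) is the default and an alpha-carbon mode is available. Sequence
neighbours (`|i - j| < 2`) are excluded, also configurable.

Edges are weighted `d_ij = -ln|C_ij|` (natural log; the base only rescales
all weights uniformly and cannot change shortest paths or communities), with
`|C|` clamped to `[1e-6, 1]` so absent correlations give large but finite
distances, and clamped edges flagged. Communities come from the
Girvan-Newman divisive algorithm: repeatedly remove the edge of highest
weighted betweenness (Brandes' algorithm with Dijkstra shortest paths;
ties broken by the lexicographically smallest residue pair for
determinism), track the unweighted modularity of every intermediate
partition, and return the partition of maximum modularity. Communities
smaller than three residues are dropped and their nodes reported as
unassigned. Intercommunity connection strength is the summed betweenness —
computed on the full graph — of the edges spanning a community pair, the
conventional proxy for signal flow; the report format is "n communities,
m pathways".

# Synthetic systems: what they emulate, and what they do not

Every stage is tested against generators with planted, recoverable ground
truth, all pure functions of their parameters and an explicit integer seed
(`withr::with_seed` localises the RNG; global state is never touched).

* **Metastable dynamics.** Overdamped Langevin (Euler-Maruyama) motion on a
  sum of inverted Gaussians plus a weak harmonic confinement
  (default 0.05 kcal/mol/A^2) that keeps the walker from wandering off the
  flat far field. The stationary density is available by quadrature, giving
  an exact Boltzmann-occupancy oracle; the integrator refuses timesteps
  beyond the stability bound of the stiffest well. This stands in for the
  open/intermediate/closed basins of a loop order parameter.
* **Loop pseudo-protein.** A two-lobe alpha-carbon bead scaffold with a
  ligand bead in the cleft, a hinge strip lining the cleft, and a loop whose
  closed conformation differs from the open one only by a planted
  displacement toward the ligand (closed loop beads land within contact
  range of the hinge; open ones do not). Trajectories couple a 1-D state
  path in `[0, 1]` to linear interpolation between the frames plus isotropic
  Gaussian jitter, so loop RMSF, loop-ligand distance, correlation
  structure and contact edges are all known by construction.
* **Planted covariance fields.** Per-frame residue displacements drawn from
  a block-structured multivariate normal applied identically to each
  Cartesian component, so the displacement-vector correlation equals the
  planted matrix exactly in expectation. Static anchor beads are appended;
  fitting the superposition on them keeps rigid-body removal from biasing
  the recovered correlations (superposing on the correlated beads themselves
  subtracts the ensemble-mean displacement and shifts correlations by
  O(1/n)).
* **Markov chains and energy tables.** Direct sampling from a planted
  row-stochastic matrix, and independent Gaussian per-frame energy
  components with planted means.

These generators emulate the *statistical structure* the analyses consume —
metastability, correlation blocks, additive energies, contact geometry.
They do not emulate force-field physics, solvent, bonded geometry or
realistic protein packing; a passing suite therefore demonstrates that the
estimators recover what was planted at realistic sample sizes, not that any
particular real system will show a particular effect.

# Numerical choices

* Kabsch: weights normalised to sum 1; `det` correction applied on the sign
  of `det(V U')`; the reported RMSD is reproduced by applying the transform
  (checked to 1e-10).
* RMSF/DCCM mean-structure iteration: tolerance 1e-6 A, cap 50 iterations.
* Eigen-decompositions of reversible transition matrices go through the
  symmetric similarity transform; the stationary vector comes from the
  leading left eigenvector, made non-negative and normalised.
* Shortest-path ties in betweenness use an absolute tolerance of 1e-9 on
  path lengths; zero-weight edges (|C| = 1) are legal.
* Degenerate inputs: empty selections error (or warn when an expression
  legitimately matches nothing); all frames in one histogram bin yields a
  single 0-valued bin with a warning; an unreachable MFPT sink reports
  `Inf` with a `reachable = FALSE` flag; a metastate left empty after
  trimming yields `NA` with a warning.

# The pipeline and problem sizes

`run_pipeline()` executes the stages over either a user trajectory (plus a
description of the loop/hinge/ligand regions) or a synthetic two-lobe
system, writes per-stage TSV/JSON plus a summary and a parameter log, and
`compare_systems()` reports side-by-side deltas (`b - a`). Stage parameters
default to the conventional values named above (0.3 mask, 4.5 A / 75%
contacts, 1 kcal/mol significance, 300 K, 100 centers / 100 iterations);
any can be overridden per run, and the test suite and demonstration runs use
desk-scale sizes — a 50-residue bead protein, 250-400 frames, 20-25
microstates, 2 metastates — chosen so the whole suite completes in about a
minute while every estimator still operates far from its small-sample limit.
Published analyses of real kinase systems operate on microseconds of
all-atom trajectory; those inputs are accepted through the same PDB/TSV
interfaces but are not reproduced by the synthetic defaults.

# Known limitations

* No binary trajectory formats (DCD/XTC); multi-model PDB and TSV only,
  behind the same trajectory contract, so a binary reader is a clean
  extension point.
* No TICA/VAMP feature learning, Bayesian MSM error bars, or transition-path
  analysis beyond MFPT.
* No GB/PB solvers, SASA, or normal-mode entropy; energy components are
  consumed, not computed.
* The Girvan-Newman implementation recomputes betweenness after every edge
  removal (exact, O(V E^2) worst case); it is intended for residue-scale
  graphs (hundreds of nodes), not arbitrary networks.
* DSSP-style secondary-structure assignment and figure rendering are out of
  scope; exports are data (TSV/JSON), not graphics.
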