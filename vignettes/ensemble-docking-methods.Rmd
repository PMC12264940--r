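---
title: "Ensemble docking for disordered proteins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking for disordered proteins: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpdock)
```

## The problem

Intrinsically disordered proteins (IDPs) have no single binding site: they
interconvert between a vast number of conformations, and a small molecule
binds them as a heterogeneous ensemble of transient complexes rather than a
lock-and-key pose. Conventional docking — one receptor structure, one
pocket — is therefore structurally inapplicable. `idpdock` implements the
ensemble alternative: dock the ligand onto *every* conformation of an input
ensemble, keep one pose per conformation, and characterize the resulting
*docked ensemble* statistically — per-residue interaction populations,
dual-residue contact maps, pose-RMSD distributions against reference bound
ensembles, and normalized-score affinity ranking.

Two docking protocols are provided behind one backend contract:

* **Per-residue docking** (grid engines, AutoDock-Vina style): for a chain
  of $n$ residues, $n$ docking calculations per conformation, each confined
  to a cubic box centred on one residue's centre of mass. The best-scoring
  of the $n$ candidate poses (under the backend's declared polarity)
  becomes the conformation's selected pose; ties go to the lowest residue
  index. This guarantees the search covers the whole chain even though a
  disordered conformation has no canonical pocket.
* **Whole-conformation docking** (confidence-ranked engines, DiffDock
  style): one calculation per conformation with an unrestricted search
  space, requesting `n_poses` (default 10) candidates and selecting the
  best. Confidence scores are declared `higher_is_better` on the backend
  spec, so the same selection logic drives both protocols.

Apo docking, holo (re)docking and cross docking are the same computation on
different inputs — docking only ever sees protein coordinates. Holo inputs
are produced by `extract_bound_frames()`, which keeps the frames whose
minimum heavy-atom protein–ligand distance is at most 6 Å (the *bound
frames*), strips the ligand, and reports the bound fraction.

## Search-box sizing

Each per-residue box is a cube of edge `edge_scale * Rg(ligand)` centred on
the residue's mass-weighted centre of mass, so the search volume scales as
$R_g^3$. The default `edge_scale = 3.92` is back-solved from published
search-space volumes of this protocol (a ligand of $R_g$ 4.23 Å with a
4561 Å$^3$ box and one of 3.53 Å with 2646 Å$^3$ both give edge/Rg ≈ 3.92).
The third published pairing (3.48 Å, 2220 Å$^3$) implies ≈ 3.75, so the
exact upstream sizing rule is not recoverable from the printed numbers
alone; rather than guess, the factor is an explicit parameter and the
default reproduces two of the three volumes within rounding. $R_g$ is
mass-weighted over all atoms (a heavy-atom-only switch exists); hydrogens
contribute negligibly by mass, so the distinction rarely matters.

## The mock backend

External engines are driven through thin adapters (PDBQT emission, a
command line carrying the box as `--center_*`/`--size_*` flags, score-table
parsing, and a structured "backend unavailable" error when the binary is
missing). The package's own science, however, is tested against a built-in
deterministic backend, `mock_backend()`: the ligand is kept rigid and its
centroid visits every point of a regular grid of spacing $g$ filling the
box; a placement scores $\sum_{\text{pairs } d \le 8} t(d)$ over
ligand-heavy/protein-heavy pairs with $t(d) = +1000$ for $d < 2$ Å (clash)
and $-\exp(-(d-3.5)^2/2)$ otherwise. Poses are returned sorted, ties broken
by lexicographic grid order. The backend deliberately samples no torsions
or rotations: the package's claims are about the *protocol* (box
construction, candidate bookkeeping, selection, downstream statistics), not
about any engine's pose quality, and a translational grid search is exactly
checkable against brute-force enumeration — which the test suite does on
hundreds of random requests. Determinism also makes every pipeline output
reproducible from its seed.

Grid definition: $\lfloor \text{edge}/g \rfloor$ cell centres per axis
(`lo + (k - 1/2) g`); an edge smaller than $g$ is an empty grid and an
error rather than a silent point evaluation.

## Conformational clustering

Ensembles are featurized as all pairwise Cα–Cα distances (rigid-motion
invariant, $n(n-1)/2$ columns). For each perplexity on a user grid, a 2-D
t-SNE embedding is computed, partitioned by k-means with fixed $k$ (default
20), and scored by the mean silhouette width *in embedding space*; the
perplexity with the best silhouette wins. The upstream procedure this
emulates does not state its feature vector, distance metric or partitioner,
so these three choices — pairwise-Cα features, k-means on the embedding,
silhouette in embedding space — are deliberate stand-ins, each exposed as
configuration. Published perplexities for the ensembles that motivated the
protocol were 1100–1800 at 2 × 10^4 frames; perplexity is data-size
dependent, so the package defaults are small (30, 50) and suit the
hundreds-of-frames fixtures used in the tests.

Cluster populations (fractions of the *full source ensemble*) weight all
downstream ensemble averages: `cluster_weighted_average()` computes
$\sum_c w_c \bar{x}_c$, and when weights are proportional to cluster sizes
this provably reduces to the plain per-frame mean (a consistency check in
the tests). Each cluster is also summarized by its mean *bend angle* — the
interior angle at the middle of three anchor Cα atoms (defaults: first,
middle, last residue), a compactness descriptor used for score–structure
correlations.

## Interaction fingerprints

Five classes are computed independently per frame and residue, each with
its own cutoff, so no class implies another:

| class | rule | default |
|---|---|---|
| contact | any ligand-heavy/residue-heavy pair | ≤ 6.0 Å |
| hydrophobic | any ligand-C/protein-C pair, protein Cα excluded | ≤ 5.0 Å |
| charge | any pair of atoms with opposite formal charges | ≤ 5.0 Å |
| hydrogen bond | donor H (on N/O/S, either side) to heavy N/O/S acceptor on the other side | ≤ 3.5 Å and ∠(D,H,A) > 150° |
| aromatic stacking | ring-centroid vector **R** short and near-normal to both rings | ‖R‖ < 5 Å, both folded angles < 45° |

Design decisions worth spelling out:

* The hydrogen-bond distance is read literally as *hydrogen* to acceptor
  (not donor-heavy to acceptor); both the cutoff and the angle are
  configurable, and the angle is interpreted as the standard ∠(D,H,A).
* Acceptors are all heavy N/O/S atoms on either partner — symmetric with
  the donor rule rather than an enumerated chemistry table.
* Protein formal charges come from neutral-pH residue templates
  (carboxylate O of Asp/Glu −1, Lys Nζ and Arg guanidinium N +1, His
  neutral); ligand charges come from the input file (`M CHG` in SDF).
  Template charges mark *charged-group atoms* for opposite-sign detection;
  they are not meant to sum to a protein net charge.
* Protein aromatic rings come from residue templates (Phe, Tyr, His, both
  Trp rings); His is treated as aromatic and neutral. Ring normals are
  plane-fit by SVD and the R-to-normal angle is folded to [0°, 90°] before
  the 45° test, removing the normal's sign ambiguity.
* Pair searches use a cell list (27-cell stencil at the query cutoff);
  tests require exact agreement with the all-pairs double loop.

Aggregation turns per-frame flags into per-residue populations (overall,
per cluster, and cluster-weighted), and the contact flags into the
dual-residue contact matrix $P(i \wedge j)$, whose diagonal is the
single-residue contact probability. Profiles and matrices are compared by
Pearson *r* and RMSE (matrices over the upper triangle plus diagonal); when
either side has zero variance, *r* is reported as missing rather than
invented.

## Pose RMSD metrics

Both metrics use heavy ligand atoms and plain atom-index correspondence.

* **Frame-matched RMSD**: docked pose vs the bound pose of the *same*
  conformation. In holo docking the protein coordinates are identical by
  construction, so the protein alignment is the identity and the ligand
  RMSD is computed directly.
* **Best-matched RMSD**: the minimum, over the bound frames of the docked
  frame's cluster, of the ligand RMSD after superposing each bound frame's
  Cα coordinates onto the docked conformation (Kabsch least squares with a
  proper-rotation correction). Restricting the scan to the matching
  cluster follows the upstream protocol; a full-ensemble switch exists,
  and because the docked frame belongs to its own cluster, best-matched ≤
  frame-matched holds frame-by-frame in holo runs — an exact property the
  tests verify on full synthetic runs.

No symmetry correction is applied (a documented limitation: a flipped
benzene ring scores as displaced); distribution summaries report the
percentage of frames below 3 Å and 5 Å, formatted `a.bb (c.dd)`.

## Score statistics

Raw scores from different engines are incomparable, so each docking method
gets one min–max scale fitted on the *pooled* scores of all ligands
compared: $x_{\text{scaled}} = (x - x_{\min})/(x_{\max} - x_{\min})$ with
$x_{\max}$ the most favorable and $x_{\min}$ the least favorable pooled
score. The best pooled score maps to exactly 1, the worst to exactly 0, and
per-ligand mean normalized scores become comparable; relative affinities
rescale the means so the tightest binder is 1.0. Uncertainties are
percentile bootstrap (default 10,000 resamples; the reported error is the
mean of the upper and lower 95% CI deviations). Percentile rather than BCa
is the simplest method consistent with "bootstrapping" alone; the method is
a switch. Ligand means are cluster-weighted when a cluster model is
supplied — the protocol's stated weighting rule — with the plain mean
available, since the upstream description leaves the choice ambiguous.
Cross-docked score tables carry an explicit caveat annotation, as relative
affinities from mismatched holo ensembles are unreliable. No score-based
pose filtering is applied before averaging. `ranking_null_probability(n)`
supplies the $1/n!$ baseline for ranking claims (1/6 for three ligands).

## The synthetic-fixture generator

Fixtures test the artifact, not protein physics. A frame is a self-avoiding
Cα trace: exact 3.8 Å virtual bonds, 3.0 Å minimum non-bonded Cα
separation, built as two arms leaving the middle residue with an opening
drawn from the target bend-angle distribution (default 148° ± 10°, matching
the compact-state mean the protocol's motivating ensembles exhibit) and
per-step directional jitter of 0.08 rad. Very small targets are
geometrically infeasible (second neighbours across the vertex collide below
≈ 47°) and error after bounded retries. Pseudo side chains are templated
per residue class — Glu-like carboxylate pair, Lys-like ammonium N⁺–H,
Phe-like six-carbon ring, Ala-like Cβ, Ser-like hydroxyl — so every
geometric classifier has real targets; a sixth `pocket` class places a
12-carbon icosahedral cage (radius 3.5 Å) whose centre is equidistant from
all cage atoms, giving hotspot-recovery tests a single strongly attractive,
spatially enclosed site that only the owning residue's box can reach.
`plant_bound_poses()` draws a target residue per frame from a given
per-residue probability vector (residual mass = unbound, parked 40 Å away)
and places the randomly oriented ligand 4 Å outward of the target's
side-chain centroid plus isotropic noise, so realized contact frequencies
converge to the planted probabilities.

What the generator does *not* emulate: realistic backbone dihedrals or
side-chain rotamers, solvent, force-field energetics, and the long-range
sequence correlations of real IDP ensembles. Passing tests therefore
demonstrate the correctness of the protocol's bookkeeping and statistics —
not that any docking engine finds true poses on real proteins.

## Numerical choices and problem sizes

* One master seed per run; per-frame seeds derived deterministically by
  frame position, so serial and parallel schedules agree. All seeds stay
  below 2³¹.
* Ties: per-residue selection → lowest residue index; mock-grid scores →
  lexicographic grid order; rank ties in affinity tables → first
  occurrence.
* Degenerate inputs error early: empty grids, coincident bend-angle
  anchors, collinear superposition point sets, all-equal score sets,
  zero-variance features.
* The test suite runs at deliberately small scale — ensembles of 4–1000
  frames, 3–21 residues, ligands of 1–11 heavy atoms, grids of ≲ 10³
  points, 1000–10,000 bootstrap resamples — chosen so the whole suite
  completes in about a minute while keeping every statistical check at ≥ 3
  standard errors of headroom.

## Limitations

Beyond the generator's simplifications: MOL2 input is not supported
(convert to SDF), PDB ligand input carries no aromaticity, no symmetry
correction in RMSDs, no π–cation or water-mediated interaction classes, and
the t-SNE featurization/partitioner stand-ins above. External-engine
adapters construct commands and parse outputs but are only exercised
against text fixtures unless an engine binary is present.
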