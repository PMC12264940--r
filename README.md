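# idpdock

Ensemble docking and bound-state analysis for intrinsically disordered
proteins (IDPs), in R.

An IDP has no single structure and no fixed binding pocket: a small
molecule binds it as a heterogeneous, rapidly interconverting ensemble of
transient complexes. `idpdock` implements the ensemble-docking answer to
this: dock the ligand onto **every** conformation of an input ensemble and
analyze the resulting *docked ensemble* — one selected pose per
conformation — statistically.

The package is aimed at structural bioinformaticians and molecular
modellers who have conformational ensembles (multi-model PDB, e.g. from MD)
and want reproducible, engine-agnostic machinery for:

* **Per-residue docking protocol** — for an *n*-residue chain, *n* docking
  calculations per conformation, each confined to a cubic box centred on
  one residue's centre of mass with edge `edge_scale * Rg(ligand)` (volume
  ∝ Rg³, default `edge_scale = 3.92`); the best-scoring candidate becomes
  the conformation's pose. A whole-conformation protocol (one unrestricted
  calculation per frame, confidence-ranked candidates) is provided behind
  the same backend contract.
* **Interaction fingerprints** — per-residue populations of contacts
  (≤ 6 Å heavy-atom), hydrophobic contacts (≤ 5 Å C–C, protein Cα
  excluded), charge contacts (≤ 5 Å opposite formal charges), hydrogen
  bonds (H…acceptor ≤ 3.5 Å, ∠(D,H,A) > 150°) and aromatic stacking
  (centroid vector ‖R‖ < 5 Å, < 45° to both ring normals), plus
  dual-residue contact matrices `P(i ∧ j)` and Pearson-r/RMSE profile
  comparisons.
* **Conformational clustering** — pairwise-Cα-distance features, 2-D t-SNE
  with silhouette-driven perplexity selection, k-means partitioning
  (default k = 20), bend-angle summaries, and cluster-population weighting
  of all ensemble averages.
* **Pose RMSD metrics** — *frame-matched* (docked pose vs the bound pose of
  the identical conformation) and *best-matched* (minimum over the
  cluster's bound poses after Cα superposition), with <3 Å / <5 Å summary
  fractions.
* **Score statistics** — per-method min–max normalization pooled across all
  ligands (`x_scaled = (x − x_min)/(x_max − x_min)`, best pooled score → 1,
  worst → 0), percentile-bootstrap errors, relative-affinity ranking
  (tightest binder = 1.0), the 1/n! random-ranking baseline, and
  bend-angle/score correlations.
* **Synthetic fixtures** — a self-avoiding Cα-trace peptide generator with
  classed pseudo side chains and planted per-residue contact
  probabilities, plus a deterministic grid-search mock backend, so the full
  pipeline runs and is testable without external engines or trajectory
  data.

External grid engines are driven through thin adapters (PDBQT preparation,
box flags, score parsing); the package never reimplements an engine's
scoring function.

## Worked example

Dock three toy ligands onto a synthetic 20-residue disordered peptide
ensemble and rank them on one joint normalized scale:

```r
library(idpdock)

ens <- generate_peptide_ensemble(
  n_res = 20,
  residue_classes = rep(c("charged-", "charged+", "aromatic",
                          "hydrophobic", "polar"), 4),
  n_frames = 8, bend_mean = 148, bend_sd = 10, seed = 1)
ens
#> <conf_ensemble> 8 frames, 20 residues, 84 atoms [synthetic]

lig47 <- generate_ligand(ring = TRUE, amine = TRUE, n_heavy = 8,
                         name = "L47like")
lig47
#> <ligand_model> L47like: 11 atoms (8 heavy), net charge +1,
#>   1 aromatic ring(s), 3 donor(s), 1 acceptor(s)

de <- per_residue_ensemble_dock(ens, lig47, mock_backend(1.25), seed = 2)
de
#> <docked_ensemble> mock_grid (lower_is_better): 8 selected poses / 8 frames
round(selected_scores(de), 2)
#> [1] -75.52 -60.31 -67.88 -58.90 -63.54 -56.53 -64.44 -62.31
```

Each frame got 20 per-residue candidates; the selected pose is the
best-scoring one. Fingerprint the docked ensemble and rank the ligands:

```r
prof <- aggregate_profiles(fingerprint_ensemble(de))

ligB <- generate_ligand(amine = TRUE, n_heavy = 6, name = "fasudil_like")
ligC <- generate_ligand(ring = TRUE, n_heavy = 7, name = "L23like")
raw <- list(
  L47like = selected_scores(de),
  fasudil_like = selected_scores(
    per_residue_ensemble_dock(ens, ligB, mock_backend(1.25), seed = 3)),
  L23like = selected_scores(
    per_residue_ensemble_dock(ens, ligC, mock_backend(1.25), seed = 4)))

scale <- fit_normalization(unlist(raw), "lower_is_better", "mock_grid")
norm <- lapply(raw, normalize_scores, scale = scale)
affinity_table(norm, n_boot = 10000, seed = 5)
#>         ligand mean_score  error relative_affinity rank
#> 1      L47like     0.6108 0.1249             1.000    1
#> 2      L23like     0.4211 0.1215             0.689    2
#> 3 fasudil_like     0.0809 0.0371             0.132    3
```

`mean_score` is the ligand's mean normalized docking score on the joint
scale (1 = most favorable score observed across all three ligands with this
method), `error` its 95% percentile-bootstrap half-width, and
`relative_affinity` the mean rescaled so the tightest binder is 1.0. With
three ligands, a random ordering would be fully correct with probability
`ranking_null_probability(3)` = 1/6.

## Command line

A thin wrapper over the same functions ships at
`system.file("cli/idpdock.R", package = "idpdock")` with subcommands
`synth | cluster | dock | fingerprint | rmsd | scores | report`, YAML
configs, `--key value` overrides and a JSON run manifest next to every
output:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/idpdock.R", package = "idpdock"))')
Rscript "$CLI" synth --seed 4 --n-res 12 --n-frames 20 --out-prefix pep
Rscript "$CLI" dock  --ensemble pep_ensemble.pdb --ligand pep_ligand.sdf \
                     --seed 4 --out-prefix run
Rscript "$CLI" scores --score-tables run_scores.tsv --out-prefix aff
```

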