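# Bound-frame extraction, cluster sampling and the two docking protocols.

test_that("the 6 Å bound-frame filter keeps 5.9 Å and drops 6.1 Å", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 2, seed = 3,
                                   residue_classes = "hydrophobic")
  lig <- point_ligand()
  # place the ligand at a controlled minimum heavy-heavy distance per frame
  place_at <- function(frame, dist) {
    P <- ens$coords[[frame]][ens$atoms$is_heavy, , drop = FALSE]
    ref <- P[1, ]
    dir <- unit(ref - colMeans(P))
    for (s in seq(dist, dist + 30, by = 0.05)) {
      cand <- ref + s * dir
      if (abs(min(cross_dist(matrix(cand, ncol = 3), P)) - dist) < 1e-6)
        return(cand)
    }
    stop("could not place ligand")
  }
  holo <- holo_ensemble(ens, lig, list(
    matrix(place_at(1, 5.9), ncol = 3),
    matrix(place_at(2, 6.1), ncol = 3)))
  res <- extract_bound_frames(holo, bound_frame_filter(6.0))
  expect_equal(res$bound_fraction, 0.5)
  expect_equal(unlist(res$ensemble$frame_ids), 1)
  expect_equal(ncol(res$ensemble$atoms), ncol(ens$atoms))  # ligand stripped
})

test_that("bound fraction is exact on a constructed 40% bound ensemble", {
  ens <- generate_peptide_ensemble(n_res = 4, n_frames = 20, seed = 8)
  lig <- point_ligand()
  bound <- rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 4)  # 40% bound
  coords <- lapply(seq_len(20), function(f) {
    if (bound[f]) matrix(ens$coords[[f]][1, ], ncol = 3)        # on a CA
    else matrix(ens$coords[[f]][1, ] + c(100, 0, 0), ncol = 3)  # far away
  })
  res <- extract_bound_frames(holo_ensemble(ens, lig, coords))
  expect_equal(res$bound_fraction, 0.40)
  # all frames bound -> 1.0
  res2 <- extract_bound_frames(
    holo_ensemble(ens, lig, lapply(ens$coords, function(m)
      matrix(m[1, ], ncol = 3))))
  expect_equal(res2$bound_fraction, 1.0)
})

test_that("cluster sampling draws without replacement and honors deficits", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 23, seed = 2)
  labels <- rep(c(0, 1), c(15, 8))
  expect_warning(
    sub <- sample_cluster_frames(ens, labels, n_per_cluster = 10, seed = 5),
    "only 8 frames")
  ids <- unlist(sub$frame_ids)
  expect_equal(length(ids), 18)       # 10 + all 8
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(sum(ids > 15), 8)      # deficit cluster taken whole
  # determinism and identity sampling
  sub2 <- suppressWarnings(
    sample_cluster_frames(ens, labels, n_per_cluster = 10, seed = 5))
  expect_identical(unlist(sub2$frame_ids), ids)
  all_of_it <- sample_cluster_frames(ens, labels, n_per_cluster = 100,
                                     seed = 1) |> suppressWarnings()
  expect_equal(sort(unlist(all_of_it$frame_ids)), 1:23)
})

test_that("per-residue docking yields one candidate per residue and one selected pose per frame", {
  ens <- generate_peptide_ensemble(n_res = 20, n_frames = 3, seed = 6)
  lig <- generate_ligand(n_heavy = 2)
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(1.0), seed = 1)
  expect_equal(length(de$selected), 3)
  for (f in 1:3) {
    expect_equal(length(de$candidates[[f]]), 20)
    expect_equal(sort(vapply(de$candidates[[f]],
                             function(p) p$origin_residue, 0L)), 1:20)
  }
})

test_that("per-residue selection equals the brute-force argmin over residue boxes", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 2, seed = 13)
  lig <- generate_ligand(n_heavy = 2)
  rg <- radius_of_gyration(lig)
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(1.0), seed = 1)
  for (f in 1:2) {
    conf <- get_conformation(ens, f)
    best <- lapply(1:3, function(r) {
      o <- brute_grid_scores(conf, lig,
                             build_residue_box(conf, r, rg), 1.0)
      min(o$scores)
    })
    expect_equal(de$selected[[f]]$raw_score, min(unlist(best)),
                 tolerance = 1e-9)
    expect_equal(de$selected[[f]]$origin_residue,
                 which.min(unlist(best)))
  }
})

test_that("score ties between residues resolve to the lower residue index", {
  # two isolated single-atom residues with identical local geometry
  conf_coords <- rbind(c(0, 0, 0), c(40, 0, 0))
  atoms <- atom_table(1:2, 1:2, c("ALA", "ALA"), c("CA", "CA"))
  ens <- conformation_ensemble(atoms, list(conf_coords))
  lig <- ligand_model(
    data.frame(name = c("C1", "C2"), element = "C", formal_charge = 0L),
    rbind(c(0, 0, 0), c(1.5, 0, 0)),
    data.frame(i = 1L, j = 2L, order = 1L))
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(1.0),
                                  edge_scale = 4, seed = 1)
  cand_scores <- vapply(de$candidates[[1]], function(p) p$raw_score, 0)
  expect_equal(cand_scores[1], cand_scores[2], tolerance = 1e-9)
  expect_equal(de$selected[[1]]$origin_residue, 1L)
})

test_that("whole-conformation docking selects the global grid optimum per frame", {
  ens <- generate_peptide_ensemble(n_res = 4, n_frames = 2, seed = 21)
  lig <- generate_ligand(n_heavy = 2)
  de <- whole_conformation_ensemble_dock(ens, lig, mock_backend(1.0),
                                         n_poses = 5, seed = 1)
  expect_equal(length(de$selected), 2)
  expect_true(all(is.na(vapply(de$selected, function(p) p$origin_residue,
                               0L))))
  for (f in 1:2) {
    conf <- get_conformation(ens, f)
    box <- idpdock:::whole_conformation_box(conf, radius_of_gyration(lig))
    o <- brute_grid_scores(conf, lig, box, 1.0)
    expect_equal(de$selected[[f]]$raw_score, min(o$scores),
                 tolerance = 1e-9)
  }
  # n_poses = 1 returns exactly the single pose as selected
  de1 <- whole_conformation_ensemble_dock(ens, lig, mock_backend(1.0),
                                          n_poses = 1, seed = 1)
  expect_equal(selected_scores(de1), selected_scores(de), tolerance = 1e-9)
})

test_that("selected scores are a lower envelope of the candidate scores", {
  ens <- generate_peptide_ensemble(n_res = 6, n_frames = 4, seed = 17)
  lig <- generate_ligand(n_heavy = 3)
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(1.0), seed = 2)
  for (f in seq_along(de$selected)) {
    cand <- vapply(de$candidates[[f]], function(p) p$raw_score, 0)
    expect_equal(de$selected[[f]]$raw_score, min(cand))
  }
})

test_that("a planted pocket hotspot dominates the selected-pose origins", {
  classes <- rep("hydrophobic", 12)
  classes[6] <- "pocket"
  ens <- generate_peptide_ensemble(n_res = 12, residue_classes = classes,
                                   n_frames = 10, seed = 19)
  lig <- generate_ligand(n_heavy = 2)
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(0.75), seed = 4)
  origins <- vapply(de$selected, function(p) p$origin_residue, 0L)
  expect_gte(mean(origins == 6), 0.95)
})
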