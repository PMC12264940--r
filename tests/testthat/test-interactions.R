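# Geometric interaction classifiers: boundary constructions, invariances,
# aggregation and comparison statistics.

test_that("charge contacts flip across the 5 Å boundary", {
  conf <- toy_conformation(c(1, 1), c("GLU", "GLU"), c("CA", "OE1"),
                           c(-2, 0, 0, 0, 0, 0))
  expect_equal(conf$atoms$formal_charge, c(0L, -1L))
  near <- fingerprint_frame(conf, point_ligand(c(4.9, 0, 0), "N", 1L))
  far <- fingerprint_frame(conf, point_ligand(c(5.1, 0, 0), "N", 1L))
  expect_true(near$flags[1, "charge"])
  expect_false(far$flags[1, "charge"])
  # same-sign charges never count
  same <- fingerprint_frame(conf, point_ligand(c(4.9, 0, 0), "O", -1L))
  expect_false(same$flags[1, "charge"])
})

test_that("hydrogen bonds need 3.5 Å H-acceptor distance and >150 degree angle", {
  acceptor_at <- function(theta_deg) {
    # acceptor placed so the D-H-A angle equals theta
    h <- c(0.96, 0, 0)
    phi <- (180 - theta_deg) * pi / 180
    h + 3.4 * c(cos(phi), sin(phi), 0)
  }
  lig <- donor_ligand(o = c(0, 0, 0), h = c(0.96, 0, 0))
  conf_at <- function(a) {
    toy_conformation(c(1, 1), c("SER", "SER"), c("CA", "OG"),
                     c(a[1], a[2] + 5, a[3], a))
  }
  good <- fingerprint_frame(conf_at(acceptor_at(170)), lig)
  bad <- fingerprint_frame(conf_at(acceptor_at(140)), lig)
  expect_true(good$flags[1, "hbond"])
  expect_false(bad$flags[1, "hbond"])
  # beyond 3.5 Å fails even at perfect geometry
  lig_far <- donor_ligand(o = c(-3.7 - 0.96, 0, 0), h = c(-3.7, 0, 0))
  conf_lin <- toy_conformation(c(1, 1), c("SER", "SER"), c("CA", "OG"),
                               c(0, 5, 0, 0, 0, 0))
  expect_false(fingerprint_frame(conf_lin, lig_far)$flags[1, "hbond"])
})

test_that("protein-side donors hydrogen-bond to ligand acceptors", {
  # Lys-like ammonium N-H pointing at a ligand oxygen acceptor
  conf <- toy_conformation(c(1, 1, 1), rep("LYS", 3),
                           c("CA", "NZ", "HZ1"),
                           c(-1.5, 0, 0, 0, 0, 0, 1.0, 0, 0))
  lig <- point_ligand(c(4.2, 0, 0), "O")  # H...O = 3.2 Å, angle 180
  fp <- fingerprint_frame(conf, lig)
  expect_true(fp$flags[1, "hbond"])
})

test_that("aromatic stacking requires closeness and near-normal alignment of R", {
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- (0:5) * pi / 3
  prot_xyz <- rbind(c(0, 0, -5),
                    cbind(1.39 * cos(ang), 1.39 * sin(ang), 0))
  conf <- toy_conformation(rep(1, 7), rep("PHE", 7),
                           c("CA", ring_names), as.vector(t(prot_xyz)))
  stacked <- fingerprint_frame(conf, ring_ligand(c(0, 0, 3.5)))
  expect_true(stacked$flags[1, "aromatic_stack"])
  # lateral offset: ||R|| = 4 but R makes 60 degrees with both normals
  offset <- fingerprint_frame(conf, ring_ligand(c(2 * sqrt(3), 0, 2)))
  expect_false(offset$flags[1, "aromatic_stack"])
  # flipped ring normal must not matter (angle folded to [0, 90])
  flipped <- ring_ligand(c(0, 0, 3.5))
  flipped$coords <- flipped$coords[6:1, ]
  expect_true(fingerprint_frame(conf, flipped)$flags[1, "aromatic_stack"])
  # centroid separation beyond 5 Å fails even when parallel
  apart <- fingerprint_frame(conf, ring_ligand(c(0, 0, 5.2)))
  expect_false(apart$flags[1, "aromatic_stack"])
})

test_that("hydrophobic contacts exclude protein Cα atoms", {
  bare_ca <- toy_conformation(1, "ALA", "CA", c(0, 0, 0))
  fp <- fingerprint_frame(bare_ca, point_ligand(c(4, 0, 0)))
  expect_false(fp$flags[1, "hydrophobic"])
  expect_true(fp$flags[1, "contact"])  # classes are independent
  with_cb <- toy_conformation(c(1, 1), c("ALA", "ALA"), c("CA", "CB"),
                              c(0, 0, 0, 0, 0, 0.5))
  expect_true(
    fingerprint_frame(with_cb,
                      point_ligand(c(4, 0, 0)))$flags[1, "hydrophobic"])
})

test_that("classifications are invariant under joint rigid motion", {
  ens <- generate_peptide_ensemble(
    n_res = 6, n_frames = 1, seed = 44,
    residue_classes = c("charged-", "charged+", "aromatic", "polar"))
  lig <- generate_ligand(ring = TRUE, amine = TRUE, n_heavy = 8)
  holo <- plant_bound_poses(ens, lig, c(0, 0, 1, 0, 0, 0), noise_sd = 0,
                            seed = 2)
  conf <- get_conformation(ens, 1)
  fp0 <- fingerprint_frame(conf, lig,
                           pose(holo$ligand_coords[[1]], 0, 1))
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- c(11, -4, 3)
  conf2 <- conf
  conf2$coords <- sweep(conf$coords %*% Q, 2, shift, "+")
  moved_pose <- pose(sweep(holo$ligand_coords[[1]] %*% Q, 2, shift, "+"),
                     0, 1)
  fp1 <- fingerprint_frame(conf2, lig, moved_pose)
  expect_identical(fp1$flags, fp0$flags)
})

test_that("enlarging cutoffs (or relaxing the angle) never decreases populations", {
  ens <- generate_peptide_ensemble(
    n_res = 8, n_frames = 20, seed = 50,
    residue_classes = c("charged-", "charged+", "aromatic", "polar"))
  lig <- generate_ligand(ring = TRUE, amine = TRUE, hbond_donor = TRUE,
                         n_heavy = 9)
  holo <- plant_bound_poses(ens, lig, rep(0.12, 8), noise_sd = 1, seed = 6)
  tight <- aggregate_profiles(fingerprint_ensemble(holo))
  loose_crit <- interaction_criteria(
    contact_cutoff = 8, hydrophobic_cutoff = 7, charge_cutoff = 7,
    hbond_ha_cutoff = 4.5, hbond_angle_min = 120,
    stack_centroid_cutoff = 7, stack_angle_max = 60)
  loose <- aggregate_profiles(fingerprint_ensemble(holo, loose_crit))
  expect_true(all(loose$populations - tight$populations >= -1e-12))
})

test_that("cell-list pair search equals the all-pairs double loop", {
  set.seed(70)
  for (rep in 1:25) {
    X <- matrix(runif(3 * sample(1:20, 1), -8, 8), ncol = 3)
    Y <- matrix(runif(3 * sample(1:20, 1), -8, 8), ncol = 3)
    cutoff <- runif(1, 1, 7)
    got <- pairs_within(X, Y, cutoff)
    want <- naive_pairs(X, Y, cutoff)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # empty inputs
  expect_equal(nrow(pairs_within(matrix(numeric(), ncol = 3),
                                 matrix(1:3, 1), 5)), 0)
})

test_that("profile aggregation averages per frame and per cluster", {
  f1 <- random_fingerprint(5, 0)
  f1$flags[3, "hbond"] <- TRUE
  f2 <- random_fingerprint(5, 0)
  prof <- aggregate_profiles(list(f1, f2))
  expect_equal(unname(prof$populations[3, "hbond"]), 0.5)
  expect_equal(sum(prof$populations) - 0.5, 0)  # everything else zero
  expect_error(aggregate_profiles(list()), "no fingerprints")
  # per-cluster + weighted combination
  prof2 <- aggregate_profiles(list(f1, f2, f1, f1), labels = c(0, 0, 1, 1),
                              populations = c(0.25, 0.75))
  expect_equal(unname(prof2$per_cluster[["0"]][3, "hbond"]), 0.5)
  expect_equal(unname(prof2$per_cluster[["1"]][3, "hbond"]), 1.0)
  expect_equal(unname(prof2$weighted[3, "hbond"]), 0.25 * 0.5 + 0.75 * 1.0)
})

test_that("dual-contact matrices match direct counting and its invariants", {
  f <- random_fingerprint(8, 0)
  f$flags[c(3, 7), "contact"] <- TRUE
  f$contacted <- c(3, 7)
  M <- dual_contact_matrix(list(f))
  expect_equal(M[3, 3], 1); expect_equal(M[7, 7], 1)
  expect_equal(M[3, 7], 1); expect_equal(M[7, 3], 1)
  expect_equal(sum(M), 4)
  set.seed(81)
  fps <- replicate(60, random_fingerprint(10, 0.4), simplify = FALSE)
  M <- dual_contact_matrix(fps)
  # direct counting oracle
  for (i in c(1, 4, 9)) for (j in c(2, 4, 10)) {
    direct <- mean(vapply(fps, function(f)
      f$flags[i, "contact"] && f$flags[j, "contact"], TRUE))
    expect_equal(M[i, j], direct)
  }
  expect_equal(M, t(M))
  for (i in 1:10) for (j in 1:10)
    expect_lte(M[i, j], min(M[i, i], M[j, j]) + 1e-12)
})

test_that("independent residue contacts give product-law off-diagonals", {
  set.seed(90)
  fps <- replicate(2000, random_fingerprint(4, 0.5), simplify = FALSE)
  M <- dual_contact_matrix(fps)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(M[1, 2] - 0.25), 3 * se)
  expect_lt(abs(M[3, 4] - 0.25), 3 * se)
})

test_that("profile comparison reproduces the direct r and RMSE formulas", {
  a <- c(0.1, 0.4, 0.9, 0.3)
  st <- compare_profiles(a, a)
  expect_equal(st$pearson_r, 1)
  expect_equal(st$rmse, 0)
  expect_equal(compare_profiles(a, 1 - a)$pearson_r, -1)
  b <- c(0.2, 0.1, 0.8, 0.5)
  st2 <- compare_profiles(a, b)
  expect_equal(st2$pearson_r, naive_pearson(a, b), tolerance = 1e-12)
  expect_equal(st2$rmse, naive_rmse(a, b), tolerance = 1e-12)
  expect_warning(st3 <- compare_profiles(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(st3$pearson_r))
  expect_equal(st3$rmse, naive_rmse(c(1, 1, 1), c(1, 2, 3)))
  # matrices compare over upper triangle + diagonal
  A <- matrix(runif(9), 3); A <- (A + t(A)) / 2
  B <- matrix(runif(9), 3); B <- (B + t(B)) / 2
  keep <- upper.tri(A, diag = TRUE)
  expect_equal(compare_profiles(A, B)$rmse, naive_rmse(A[keep], B[keep]),
               tolerance = 1e-12)
})
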