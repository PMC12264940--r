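# Shared fixture builders and independent oracles. Oracles are written as
# naive loops, deliberately separate from the package's vectorized /
# cell-list implementations.

# Build a conformation directly from per-atom vectors.
toy_conformation <- function(res_index, res_name, atom_name, coords,
                             element = NULL, formal_charge = NULL,
                             frame_id = 1L) {
  atoms <- atom_table(res_index, res_index + 120L, res_name, atom_name,
                      element = element, formal_charge = formal_charge)
  ens <- conformation_ensemble(atoms, list(matrix(coords, ncol = 3,
                                                  byrow = TRUE)))
  get_conformation(ens, 1)
}

# Minimal single-atom-per-residue peptide; all CA carbons.
toy_ca_chain <- function(coords) {
  n <- nrow(matrix(coords, ncol = 3, byrow = TRUE))
  toy_conformation(seq_len(n), rep("ALA", n), rep("CA", n), coords)
}

# One-heavy-atom ligand with optional formal charge.
point_ligand <- function(at = c(0, 0, 0), element = "C", charge = 0L) {
  ligand_model(
    data.frame(name = paste0(element, 1), element = element,
               formal_charge = as.integer(charge)),
    matrix(at, ncol = 3),
    data.frame(i = integer(), j = integer(), order = integer()),
    acceptors = if (element %in% c("N", "O", "S")) 1L else integer(),
    net_charge = as.integer(charge))
}

# Planar aromatic six-carbon ring ligand centered at `center`, normal +z.
ring_ligand <- function(center = c(0, 0, 0), radius = 1.39) {
  ang <- (0:5) * pi / 3
  xyz <- cbind(center[1] + radius * cos(ang),
               center[2] + radius * sin(ang),
               center[3])
  ligand_model(
    data.frame(name = paste0("C", 1:6), element = "C",
               formal_charge = 0L),
    xyz,
    data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
    aromatic_rings = list(1:6))
}

# Ligand with one O-H donor; donor heavy at `o`, hydrogen at `h`.
donor_ligand <- function(o = c(0, 0, 0), h = c(0.96, 0, 0)) {
  ligand_model(
    data.frame(name = c("O1", "H2"), element = c("O", "H"),
               formal_charge = 0L),
    rbind(o, h),
    data.frame(i = 1L, j = 2L, order = 1L),
    donors = matrix(c(1L, 2L), ncol = 2),
    acceptors = 1L)
}

# ---- independent oracles ------------------------------------------------

# All-pairs double loop neighbor search.
naive_pairs <- function(X, Y, cutoff) {
  X <- matrix(X, ncol = 3); Y <- matrix(Y, ncol = 3)
  out <- NULL
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      d <- sqrt(sum((X[i, ] - Y[j, ])^2))
      if (d <= cutoff) out <- rbind(out, c(i, j, d))
    }
  }
  if (is.null(out)) return(data.frame(i = integer(), j = integer(),
                                      d = numeric()))
  data.frame(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
             d = out[, 3])
}

# Brute-force enumeration of every mock-grid placement and score, with
# explicit loops; returns scores in lexicographic grid order.
brute_grid_scores <- function(conf, ligand, box, g) {
  n <- floor(box$edge / g + 1e-9)
  stopifnot(n >= 1)
  axis_pts <- function(c0) c0 - box$edge / 2 + (seq_len(n) - 0.5) * g
  xs <- axis_pts(box$center[1]); ys <- axis_pts(box$center[2])
  zs <- axis_pts(box$center[3])
  P <- conf$coords[conf$atoms$is_heavy, , drop = FALSE]
  L0 <- ligand$coords[ligand$atoms$is_heavy, , drop = FALSE]
  cen <- colMeans(ligand$coords)
  pts <- NULL; scores <- NULL
  for (x in xs) for (y in ys) for (z in zs) {
    s <- 0
    for (a in seq_len(nrow(L0))) {
      pa <- L0[a, ] - cen + c(x, y, z)
      for (b in seq_len(nrow(P))) {
        d <- sqrt(sum((pa - P[b, ])^2))
        if (d <= 8) s <- s + if (d < 2) 1000 else -exp(-(d - 3.5)^2 / 2)
      }
    }
    pts <- rbind(pts, c(x, y, z)); scores <- c(scores, s)
  }
  list(points = pts, scores = scores)
}

# Random small docking request for oracle-equality sweeps.
random_dock_request <- function() {
  n_prot <- sample(3:8, 1)
  conf <- toy_ca_chain(matrix(stats::runif(n_prot * 3, -4, 4), n_prot))
  n_lig <- sample(1:3, 1)
  lig <- ligand_model(
    data.frame(name = paste0("C", seq_len(n_lig)), element = "C",
               formal_charge = 0L),
    matrix(stats::runif(n_lig * 3, -1, 1), n_lig),
    data.frame(i = integer(), j = integer(), order = integer()))
  box <- search_box(stats::runif(3, -2, 2), stats::runif(1, 2, 5))
  g <- stats::runif(1, 0.8, 1.6)
  list(conf = conf, ligand = lig, box = box, g = g)
}

# Direct Pearson r and RMSE formulas.
naive_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}
naive_rmse <- function(a, b) sqrt(mean((a - b)^2))

# Random frame fingerprint with independent per-residue contact draws.
random_fingerprint <- function(n_res, p = 0.5) {
  flags <- matrix(FALSE, n_res, 5,
                  dimnames = list(NULL, c("contact", "hydrophobic",
                                          "aromatic_stack", "charge",
                                          "hbond")))
  flags[, "contact"] <- stats::runif(n_res) < p
  structure(list(flags = flags, contacted = which(flags[, "contact"])),
            class = "frame_fingerprint")
}
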