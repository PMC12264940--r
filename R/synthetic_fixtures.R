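# Synthetic disordered-peptide fixtures.
#
# A Cα-trace backbone (fixed 3.8 Å virtual bonds, 3.0 Å self-avoidance)
# with templated pseudo side chains per residue class, a controllable
# end-bend angle, toy ligands with a pharmacophore menu, and ligand-bound
# ensembles with planted per-residue contact probabilities. Fixtures test
# the artifact, not protein physics: every geometric classifier and both
# RMSD metrics can be exercised with planted ground truth and no external
# data.

.CLASS_RESIDUE <- c("charged-" = "GLU", "charged+" = "LYS",
                    aromatic = "PHE", hydrophobic = "ALA", polar = "SER",
                    pocket = "CAG")

.CA_BOND <- 3.8       # virtual Cα-Cα bond length (Å)
.SELF_AVOID <- 3.0    # minimum non-bonded Cα-Cα distance (Å)

# Side-chain template for one residue class: atom names and positions as
# (s, w) in-plane coefficients, where s is the outward side direction and w
# a perpendicular in-plane direction. Hydrogens included on donors.
side_chain_atoms <- function(class, ca, s, w) {
  hex <- function(center, r = 1.39) {
    ang <- (0:5) * pi / 3
    lapply(seq_along(ang), function(k)
      center + r * (cos(ang[k]) * s + sin(ang[k]) * w))
  }
  switch(class,
    "charged-" = list(CB = ca + 1.5 * s,
                      OE1 = ca + 2.8 * s + 0.6 * w,
                      OE2 = ca + 2.8 * s - 0.6 * w),
    "charged+" = list(CB = ca + 1.5 * s,
                      NZ = ca + 3.0 * s,
                      HZ1 = ca + 4.0 * s),
    aromatic = {
      ring <- hex(ca + 4.0 * s)
      names(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      c(list(CB = ca + 1.5 * s), ring)
    },
    hydrophobic = list(CB = ca + 1.5 * s),
    polar = list(OG = ca + 1.5 * s,
                 HG = ca + 2.46 * s),
    pocket = {
      # spherical 12-carbon cage (icosahedron, radius 3.5 Å) emulating a
      # compact binding pocket: its center is equidistant from every cage
      # atom, a single strongly attractive, spatially enclosed site
      phi <- (1 + sqrt(5)) / 2
      verts <- rbind(
        c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
        c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
        c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
      verts <- verts / sqrt(1 + phi^2) * 3.5
      center <- ca + 2.5 * s
      n3 <- unit(cross3(s, w))
      B <- cbind(s, w, n3)
      cage <- lapply(seq_len(12), function(k)
        center + as.vector(B %*% verts[k, ]))
      names(cage) <- sprintf("CG%d", seq_len(12))
      c(list(CB = ca + 1.5 * s), cage)
    },
    stop("unknown residue class: ", class)
  )
}

# One self-avoiding Cα trace with the bend angle (first-middle-last) drawn
# around `theta` degrees. Two arms leave the middle residue with an opening
# of theta; per-step directions carry small isotropic jitter.
build_backbone <- function(n_res, theta, jitter = 0.08) {
  m <- (n_res + 1L) %/% 2L
  th <- theta * pi / 180
  # random frame
  R <- random_rotation()
  u <- R[, 1]
  v <- as.vector(R %*% c(cos(th), sin(th), 0))
  step <- function(base) unit(base + stats::rnorm(3, 0, jitter)) * .CA_BOND
  pos <- matrix(0, n_res, 3)
  for (i in seq(m - 1, 1))  pos[i, ] <- pos[i + 1, ] + step(u)
  for (i in seq(m + 1, n_res)) pos[i, ] <- pos[i - 1, ] + step(v)
  pos
}

backbone_ok <- function(pos) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  for (i in seq_len(nrow(pos) - 1)) d[i, i + 1] <- d[i + 1, i] <- Inf
  min(d) >= .SELF_AVOID
}

#' Generate a synthetic disordered-peptide ensemble
#'
#' Each frame is a self-avoiding Cα trace with exact 3.8 Å virtual bonds
#' whose end-bend angle (first-middle-last Cα) is drawn from a normal target
#' distribution, decorated with templated pseudo side chains per residue
#' class: a carboxylate O pair for `charged-` (Glu-like), an ammonium
#' N(+)-H for `charged+` (Lys-like), a planar six-carbon ring for
#' `aromatic` (Phe-like), an aliphatic carbon for `hydrophobic` (Ala-like),
#' a hydroxyl O-H for `polar` (Ser-like), and a spherical 12-carbon cage for
#' `pocket` (a compact, strongly attractive binding-pocket stand-in used in
#' hotspot-recovery tests). Deterministic given `seed`.
#'
#' @param n_res residue count (>= 3).
#' @param residue_classes per-residue class tags (recycled); any of
#'   `charged-`, `charged+`, `aromatic`, `hydrophobic`, `polar`.
#' @param n_frames frame count (>= 1).
#' @param bend_mean,bend_sd target bend-angle distribution (degrees).
#' @param seed integer seed.
#' @param max_retries per-frame retries before declaring the compactness
#'   infeasible.
#' @return a `conf_ensemble` tagged `synthetic`.
#' @export
generate_peptide_ensemble <- function(n_res = 20,
                                      residue_classes = c("charged-",
                                                          "hydrophobic"),
                                      n_frames = 100,
                                      bend_mean = 148, bend_sd = 10,
                                      seed = 1L, max_retries = 200) {
  if (n_res < 3) stop("need at least 3 residues")
  if (n_frames < 1) stop("need at least 1 frame")
  classes <- rep_len(residue_classes, n_res)
  if (!all(classes %in% names(.CLASS_RESIDUE)))
    stop("unknown residue class(es): ",
         paste(setdiff(classes, names(.CLASS_RESIDUE)), collapse = ", "))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  res_names <- .CLASS_RESIDUE[classes]
  coords <- vector("list", n_frames)
  atoms <- NULL
  for (f in seq_len(n_frames)) {
    bb <- NULL
    for (try in seq_len(max_retries)) {
      theta <- min(178, max(20, stats::rnorm(1, bend_mean, bend_sd)))
      cand <- build_backbone(n_res, theta)
      if (backbone_ok(cand)) { bb <- cand; break }
    }
    if (is.null(bb))
      stop("could not build a self-avoiding chain at the requested ",
           "compactness after ", max_retries, " retries")
    # side chains: outward directions perpendicular to the local backbone
    names_f <- character(); res_idx <- integer(); xyz <- NULL
    for (r in seq_len(n_res)) {
      prev <- bb[max(r - 1, 1), ]; nxt <- bb[min(r + 1, n_res), ]
      axis <- nxt - prev
      if (vnorm(axis) < 1e-6) axis <- c(1, 0, 0)
      ref <- stats::rnorm(3)
      s <- unit(perp_component(axis, ref)) * (if (r %% 2) 1 else -1)
      w <- unit(cross3(unit(axis), s))
      sc <- side_chain_atoms(classes[r], bb[r, ], s, w)
      names_f <- c(names_f, "CA", names(sc))
      res_idx <- c(res_idx, rep(r, 1 + length(sc)))
      xyz <- rbind(xyz, bb[r, ], do.call(rbind, sc))
    }
    if (is.null(atoms)) {
      atoms <- atom_table(res_idx, res_idx + 120L, res_names[res_idx],
                          names_f)
    }
    coords[[f]] <- unname(xyz)
  }
  conformation_ensemble(atoms, coords, source_tag = "synthetic")
}

# Component of `ref` orthogonal to `axis`.
perp_component <- function(axis, ref) {
  a <- unit(axis)
  p <- ref - sum(ref * a) * a
  if (vnorm(p) < 1e-8) p <- cross3(a, c(0, 0, 1))
  p
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a toy ligand with a pharmacophore menu
#'
#' Builds a flat, valid `ligand_model`: optionally one aromatic six-carbon
#' ring, one protonated amine (N+ with three hydrogens, a charge center and
#' hydrogen-bond donor), one hydroxyl (neutral donor), and aliphatic carbons
#' filling up to `n_heavy` heavy atoms.
#'
#' @param ring include an aromatic ring (6 heavy atoms).
#' @param amine include a protonated amine (+1, 1 heavy atom).
#' @param hbond_donor include a hydroxyl O-H (1 heavy atom).
#' @param n_heavy total heavy atoms (must accommodate the requested
#'   features).
#' @param name ligand tag.
#' @return a `ligand_model`.
#' @export
generate_ligand <- function(ring = FALSE, amine = FALSE,
                            hbond_donor = FALSE, n_heavy = 6,
                            name = "toy") {
  need <- 6 * ring + amine + hbond_donor
  if (n_heavy < max(1, need))
    stop("contradictory spec: requested features need ", need,
         " heavy atoms but n_heavy = ", n_heavy)
  elements <- character(); xyz <- NULL
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  charges <- integer(); rings_ <- list()
  donors <- matrix(integer(), ncol = 2)
  add_atom <- function(el, pos, q = 0L) {
    elements <<- c(elements, el)
    xyz <<- rbind(xyz, pos)
    charges <<- c(charges, q)
    length(elements)
  }
  add_bond <- function(i, j, o = 1L) {
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = o))
  }
  anchor <- NULL  # last heavy atom to chain from
  if (ring) {
    ang <- (0:5) * pi / 3
    idx <- vapply(ang, function(a)
      add_atom("C", 1.395 * c(cos(a), sin(a), 0)), 0L)
    for (k in 1:6) add_bond(idx[k], idx[k %% 6 + 1], 4L)
    rings_ <- list(idx)
    anchor <- idx[1]
  }
  x0 <- if (ring) 1.395 + 1.5 else 0
  place <- function(k) c(x0 + 1.5 * (k - 1), 0.4 * (k %% 2), 0)
  k <- 0
  if (amine) {
    k <- k + 1
    n_idx <- add_atom("N", place(k), 1L)
    if (!is.null(anchor)) add_bond(anchor, n_idx)
    anchor <- n_idx
    for (h in 1:3) {
      hpos <- place(k) + c(0, 0.4, 0) + 1.0 *
        c(cos(2 * pi * h / 3), 0.3, sin(2 * pi * h / 3)) / vnorm(c(cos(2 * pi * h / 3), 0.3, sin(2 * pi * h / 3)))
      h_idx <- add_atom("H", hpos)
      add_bond(n_idx, h_idx)
      donors <- rbind(donors, c(n_idx, h_idx))
    }
  }
  if (hbond_donor) {
    k <- k + 1
    o_idx <- add_atom("O", place(k))
    if (!is.null(anchor)) add_bond(anchor, o_idx)
    anchor <- o_idx
    h_idx <- add_atom("H", place(k) + c(0.6, 0.75, 0))
    add_bond(o_idx, h_idx)
    donors <- rbind(donors, c(o_idx, h_idx))
  }
  while (sum(elements != "H") < n_heavy) {
    k <- k + 1
    c_idx <- add_atom("C", place(k))
    if (!is.null(anchor)) add_bond(anchor, c_idx)
    anchor <- c_idx
  }
  atoms <- data.frame(
    name = paste0(elements, seq_along(elements)),
    element = elements, formal_charge = charges,
    stringsAsFactors = FALSE)
  acceptors <- which(elements %in% c("N", "O", "S"))
  ligand_model(atoms, xyz, bonds, rings_, donors, acceptors,
               rotatable_bonds = 0L, net_charge = sum(charges),
               name = name)
}

#' Plant ligand-bound poses with known per-residue contact probabilities
#'
#' For each frame, a target residue is drawn with probability proportional
#' to `contact_probs` (the frame is left unbound with the residual
#' probability 1 - sum). Bound frames place the (randomly oriented) ligand
#' centroid 4.0 Å outward from the target residue's side-chain centroid,
#' plus isotropic Gaussian noise; unbound frames park the ligand
#' `unbound_distance` away from the protein. Realized per-residue contact
#' frequencies converge to `contact_probs` as the frame count grows.
#'
#' @param ens a `conf_ensemble`.
#' @param ligand a `ligand_model`.
#' @param contact_probs per-residue probabilities (length n_res, sum <= 1).
#' @param noise_sd isotropic placement noise (Å).
#' @param seed integer seed.
#' @param unbound_distance centroid offset for unbound frames (Å).
#' @return a `holo_ensemble`; the drawn target residues are attached as
#'   attribute `planted_residue` (NA for unbound frames).
#' @export
plant_bound_poses <- function(ens, ligand, contact_probs, noise_sd = 0.5,
                              seed = 1L, unbound_distance = 40) {
  nr <- n_residues(ens)
  if (length(contact_probs) != nr)
    stop("contact_probs must have one entry per residue")
  if (any(contact_probs < 0) || sum(contact_probs) > 1 + 1e-9)
    stop("contact_probs must be non-negative and sum to at most 1")
  if (all(contact_probs == 0))
    warning("all contact probabilities zero: every frame left unbound")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  offsets <- sweep(ligand$coords, 2, colMeans(ligand$coords))
  cum <- cumsum(contact_probs)
  targets <- integer(n_frames(ens))
  lig_coords <- vector("list", n_frames(ens))
  for (f in seq_len(n_frames(ens))) {
    conf <- get_conformation(ens, f)
    u <- stats::runif(1)
    target <- if (u <= cum[nr]) which(u <= cum)[1] else NA_integer_
    targets[f] <- target
    rot <- random_rotation()
    if (is.na(target)) {
      dir <- unit(stats::rnorm(3))
      center <- center_of_mass(conf$coords, conf$atoms$mass) +
        unbound_distance * dir
    } else {
      rows <- residue_atom_rows(conf, target)
      side <- rows[conf$atoms$atom_name[rows] != "CA"]
      if (length(side) == 0) side <- rows
      sc <- colMeans(conf$coords[side, , drop = FALSE])
      ca <- conf$coords[rows[conf$atoms$atom_name[rows] == "CA"][1], ]
      out_dir <- if (vnorm(sc - ca) > 1e-6) unit(sc - ca) else
        unit(stats::rnorm(3))
      center <- sc + 4.0 * out_dir + stats::rnorm(3, 0, noise_sd)
    }
    lig_coords[[f]] <- sweep(offsets %*% t(rot), 2, center, "+")
  }
  out <- holo_ensemble(ens, ligand, lig_coords)
  attr(out, "planted_residue") <- targets
  out
}
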