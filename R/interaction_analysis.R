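# Geometric classification of protein-ligand interactions per frame, and
# aggregation into per-residue populations and dual-residue contact maps.
#
# Five classes, each with its own cutoff (classes are computed
# independently; a hydrogen bond at 3.4 Å says nothing about the 6 Å
# contact flag):
#   contact      any ligand-heavy / residue-heavy pair within 6.0 Å
#   hydrophobic  any ligand-C / protein-C pair within 5 Å, protein Cα excluded
#   charge       any pair of atoms with opposite formal charges within 5 Å
#   hbond        donor hydrogen (H on N/O/S, either side) within 3.5 Å of a
#                heavy N/O/S acceptor on the other side, donor-H-acceptor
#                angle > 150°
#   aromatic     ring-centroid separation ||R|| < 5 Å with the angle between
#                R and each ring normal (folded to [0°, 90°]) below 45°

.INTERACTION_CLASSES <- c("contact", "hydrophobic", "aromatic_stack",
                          "charge", "hbond")

#' Geometric interaction criteria
#'
#' @param contact_cutoff heavy-atom contact cutoff (Å).
#' @param hydrophobic_cutoff carbon-carbon cutoff (Å).
#' @param charge_cutoff opposite-formal-charge cutoff (Å).
#' @param hbond_ha_cutoff hydrogen-to-acceptor cutoff (Å); the distance is
#'   measured H to acceptor, not donor-heavy to acceptor.
#' @param hbond_angle_min minimum donor-hydrogen-acceptor angle (degrees).
#' @param stack_centroid_cutoff ring-centroid separation cutoff (Å).
#' @param stack_angle_max maximum R-to-normal angle for both rings (degrees).
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(contact_cutoff = 6.0,
                                 hydrophobic_cutoff = 5.0,
                                 charge_cutoff = 5.0,
                                 hbond_ha_cutoff = 3.5,
                                 hbond_angle_min = 150,
                                 stack_centroid_cutoff = 5.0,
                                 stack_angle_max = 45) {
  crit <- list(contact_cutoff = contact_cutoff,
               hydrophobic_cutoff = hydrophobic_cutoff,
               charge_cutoff = charge_cutoff,
               hbond_ha_cutoff = hbond_ha_cutoff,
               hbond_angle_min = hbond_angle_min,
               stack_centroid_cutoff = stack_centroid_cutoff,
               stack_angle_max = stack_angle_max)
  if (any(unlist(crit) <= 0)) stop("all cutoffs must be > 0")
  if (hbond_angle_min >= 180 || stack_angle_max >= 180)
    stop("angle criteria must lie in (0, 180)")
  structure(crit, class = "interaction_criteria")
}

# ---- neighbor search ----------------------------------------------------

#' Cross-set neighbor pairs within a cutoff (cell list)
#'
#' Returns every (i, j) with ||X[i,] - Y[j,]|| <= cutoff, found through a
#' cell list of width `cutoff` (27-cell stencil). Output is identical to the
#' all-pairs double loop.
#'
#' @param X,Y coordinate matrices (n x 3, m x 3).
#' @param cutoff distance cutoff (Å).
#' @return data.frame with columns i, j, d.
#' @export
pairs_within <- function(X, Y, cutoff) {
  X <- matrix(X, ncol = 3); Y <- matrix(Y, ncol = 3)
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (nrow(X) == 0 || nrow(Y) == 0) return(empty)
  org <- pmin(apply(X, 2, min), apply(Y, 2, min))
  cX <- floor(sweep(X, 2, org) / cutoff)
  cY <- floor(sweep(Y, 2, org) / cutoff)
  keyY <- paste(cY[, 1], cY[, 2], cY[, 3])
  ymap <- split(seq_len(nrow(Y)), keyY)
  xmap <- split(seq_len(nrow(X)), paste(cX[, 1], cX[, 2], cX[, 3]))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  for (kx in names(xmap)) {
    cc <- as.integer(strsplit(kx, " ", fixed = TRUE)[[1]])
    nb_keys <- paste(cc[1] + offs[, 1], cc[2] + offs[, 2], cc[3] + offs[, 3])
    cand <- unlist(ymap[nb_keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    xi <- xmap[[kx]]
    d <- cross_dist(X[xi, , drop = FALSE], Y[cand, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      out_i <- c(out_i, xi[hit[, 1]])
      out_j <- c(out_j, cand[hit[, 2]])
      out_d <- c(out_d, d[hit])
    }
  }
  ord <- order(out_i, out_j)
  data.frame(i = out_i[ord], j = out_j[ord], d = out_d[ord])
}

# ---- per-frame classification ------------------------------------------

# Protein donor (heavy, H) pairs: hydrogens within covalent range (1.3 Å) of
# an N/O/S heavy atom in the same residue.
protein_donors <- function(conf) {
  a <- conf$atoms
  hs <- which(a$element == "H")
  out <- matrix(integer(), ncol = 2)
  for (h in hs) {
    cand <- which(a$res_index == a$res_index[h] &
                    a$element %in% c("N", "O", "S"))
    if (length(cand) == 0) next
    d <- cross_dist(conf$coords[h, , drop = FALSE],
                    conf$coords[cand, , drop = FALSE])
    k <- which.min(d)
    if (d[k] < 1.3) out <- rbind(out, c(cand[k], h))
  }
  out
}

# Aromatic ring atom-row sets present in a conformation, from residue
# templates (Phe, Tyr, His; both Trp rings).
protein_rings <- function(conf) {
  a <- conf$atoms
  rings <- list()
  for (r in unique(a$res_index)) {
    tmpl <- .PROTEIN_RING_TEMPLATES[[a$res_name[a$res_index == r][1]]]
    if (is.null(tmpl)) next
    rows <- which(a$res_index == r)
    for (ring_names in tmpl) {
      hit <- rows[match(ring_names, a$atom_name[rows])]
      if (!anyNA(hit)) rings <- c(rings, list(hit))
    }
  }
  rings
}

# Centroid and unit normal of a ring given its coordinates (plane fit by
# SVD; the normal is the direction of least variance).
ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  sv <- svd(sweep(coords, 2, centroid))
  list(centroid = centroid, normal = unit(sv$v[, 3]))
}

# Angle between a vector and a ring normal, folded to [0, 90] to remove the
# sign ambiguity of the normal.
folded_normal_angle <- function(v, normal) {
  ang <- vec_angle_deg(v, normal)
  if (ang > 90) 180 - ang else ang
}

#' Classify the protein-ligand interactions of one frame
#'
#' @param conf a `conformation`.
#' @param ligand a `ligand_model`.
#' @param pose a `pose` (ligand coordinates for this frame); defaults to the
#'   ligand's own reference coordinates.
#' @param criteria an `interaction_criteria`.
#' @return object of class `frame_fingerprint`: `flags`, an n_res x 5
#'   logical matrix (columns contact, hydrophobic, aromatic_stack, charge,
#'   hbond), and `contacted`, the indices of contacted residues.
#' @export
fingerprint_frame <- function(conf, ligand, pose = NULL,
                              criteria = interaction_criteria()) {
  lig_xyz <- if (is.null(pose)) ligand$coords else pose$ligand_coords
  if (nrow(lig_xyz) != nrow(ligand$atoms))
    stop("pose does not match the ligand atom ordering")
  a <- conf$atoms
  nres <- n_residues(conf)
  flags <- matrix(FALSE, nres, length(.INTERACTION_CLASSES),
                  dimnames = list(NULL, .INTERACTION_CLASSES))

  mark <- function(cls, protein_rows) {
    if (length(protein_rows))
      flags[unique(a$res_index[protein_rows]), cls] <<- TRUE
  }

  # contact: heavy-heavy within 6 Å
  p_heavy <- which(a$is_heavy)
  l_heavy <- which(ligand$atoms$is_heavy)
  hits <- pairs_within(conf$coords[p_heavy, , drop = FALSE],
                       lig_xyz[l_heavy, , drop = FALSE],
                       criteria$contact_cutoff)
  mark("contact", p_heavy[hits$i])

  # hydrophobic: C-C within 5 Å, protein Cα excluded
  p_c <- which(a$element == "C" & a$atom_name != "CA")
  l_c <- which(ligand$atoms$element == "C")
  hits <- pairs_within(conf$coords[p_c, , drop = FALSE],
                       lig_xyz[l_c, , drop = FALSE],
                       criteria$hydrophobic_cutoff)
  mark("hydrophobic", p_c[hits$i])

  # charge: opposite formal charges within 5 Å
  for (sgn in c(1L, -1L)) {
    p_q <- which(sign(a$formal_charge) == sgn)
    l_q <- which(sign(ligand$atoms$formal_charge) == -sgn)
    hits <- pairs_within(conf$coords[p_q, , drop = FALSE],
                         lig_xyz[l_q, , drop = FALSE],
                         criteria$charge_cutoff)
    mark("charge", p_q[hits$i])
  }

  # hydrogen bonds, both directions
  p_donors <- protein_donors(conf)
  p_acc <- which(a$is_heavy & a$element %in% c("N", "O", "S"))
  check_hbonds <- function(donors, donor_xyz, acceptors, acceptor_xyz) {
    found <- integer()
    if (nrow(donors) == 0 || length(acceptors) == 0) return(found)
    for (k in seq_len(nrow(donors))) {
      hv <- donor_xyz[donors[k, 1], ]; hh <- donor_xyz[donors[k, 2], ]
      d <- cross_dist(matrix(hh, ncol = 3),
                      acceptor_xyz[acceptors, , drop = FALSE])
      for (m in which(d <= criteria$hbond_ha_cutoff)) {
        ang <- angle_deg(hv, hh, acceptor_xyz[acceptors[m], ])
        if (ang > criteria$hbond_angle_min)
          found <- c(found, k, acceptors[m])
      }
    }
    found
  }
  # protein donor -> ligand acceptor
  hit <- check_hbonds(p_donors, conf$coords, ligand$acceptors, lig_xyz)
  if (length(hit))
    mark("hbond", p_donors[hit[seq(1, length(hit), 2)], 1])
  # ligand donor -> protein acceptor
  hit <- check_hbonds(ligand$donors, lig_xyz, p_acc, conf$coords)
  if (length(hit)) mark("hbond", hit[seq(2, length(hit), 2)])

  # aromatic stacking
  p_rings <- protein_rings(conf)
  if (length(p_rings) && length(ligand$aromatic_rings)) {
    for (pr in p_rings) {
      pg <- ring_geometry(conf$coords[pr, , drop = FALSE])
      for (lr in ligand$aromatic_rings) {
        lg <- ring_geometry(lig_xyz[lr, , drop = FALSE])
        R <- lg$centroid - pg$centroid
        if (vnorm(R) < criteria$stack_centroid_cutoff &&
            folded_normal_angle(R, pg$normal) < criteria$stack_angle_max &&
            folded_normal_angle(R, lg$normal) < criteria$stack_angle_max) {
          mark("aromatic_stack", pr[1])
        }
      }
    }
  }

  structure(list(flags = flags, contacted = which(flags[, "contact"])),
            class = "frame_fingerprint")
}

#' Fingerprint every frame of a docked or holo ensemble
#'
#' @param x a `docked_ensemble` or `holo_ensemble`.
#' @param criteria an `interaction_criteria`.
#' @return list of `frame_fingerprint`, one per (non-failed) frame.
#' @export
fingerprint_ensemble <- function(x, criteria = interaction_criteria()) {
  if (inherits(x, "docked_ensemble")) {
    kept <- setdiff(seq_len(n_frames(x$ensemble)), x$failed_frames)
    return(lapply(seq_along(kept), function(k) {
      fingerprint_frame(get_conformation(x$ensemble, kept[k]), x$ligand,
                        x$selected[[k]], criteria)
    }))
  }
  if (inherits(x, "holo_ensemble")) {
    return(lapply(seq_len(n_frames(x$protein)), function(i) {
      fingerprint_frame(get_conformation(x$protein, i), x$ligand,
                        pose(x$ligand_coords[[i]], NA_real_,
                             x$protein$frame_ids[[i]]),
                        criteria)
    }))
  }
  stop("cannot fingerprint an object of class ", class(x)[1])
}

# ---- aggregation --------------------------------------------------------

#' Aggregate frame fingerprints into per-residue interaction populations
#'
#' @param fingerprints list of `frame_fingerprint`.
#' @param labels optional per-frame cluster labels; adds per-cluster profiles.
#' @param populations optional per-cluster source-ensemble populations
#'   (summing to 1, ordered by sorted cluster id); adds the cluster-weighted
#'   ensemble profile.
#' @return object of class `interaction_profile`: `populations` (n_res x 5
#'   matrix of fractions), `n_frames`, and optionally `per_cluster` (named
#'   list) and `weighted`.
#' @export
aggregate_profiles <- function(fingerprints, labels = NULL,
                               populations = NULL) {
  if (length(fingerprints) == 0) stop("no fingerprints to aggregate")
  pop_of <- function(fps) {
    Reduce(`+`, lapply(fps, function(f) f$flags * 1)) / length(fps)
  }
  out <- list(populations = pop_of(fingerprints),
              n_frames = length(fingerprints))
  if (!is.null(labels)) {
    if (length(labels) != length(fingerprints))
      stop("labels must cover all fingerprints")
    ids <- sort(unique(labels))
    out$per_cluster <- lapply(ids, function(c) pop_of(fingerprints[labels == c]))
    names(out$per_cluster) <- ids
    if (!is.null(populations)) {
      if (length(populations) != length(ids))
        stop("one population weight required per cluster")
      w <- Reduce(`+`, Map(function(p, wt) p * wt, out$per_cluster,
                           populations))
      out$weighted <- w / sum(populations)
    }
  }
  structure(out, class = "interaction_profile")
}

#' Dual-residue contact probability matrix
#'
#' Entry (i, j) is the fraction of frames in which residues i and j are both
#' contacted by the ligand; the diagonal is the per-residue contact
#' probability.
#'
#' @param fingerprints list of `frame_fingerprint`.
#' @return symmetric n_res x n_res matrix of probabilities.
#' @export
dual_contact_matrix <- function(fingerprints) {
  if (length(fingerprints) == 0) stop("no fingerprints")
  C <- vapply(fingerprints, function(f) f$flags[, "contact"] * 1,
              numeric(nrow(fingerprints[[1]]$flags)))
  C <- matrix(C, ncol = length(fingerprints))
  tcrossprod(C) / length(fingerprints)
}

#' Pearson r and RMSE between two profiles or matrices
#'
#' Vectors are compared elementwise; square matrices over the upper triangle
#' plus diagonal. If either side has zero variance, r is undefined and
#' returned as NA with a warning (the RMSE is still returned).
#'
#' @param a,b numeric vectors or equally-sized square matrices.
#' @return object of class `comparison_stats` with fields `pearson_r`,
#'   `rmse`, `n`.
#' @export
compare_profiles <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    if (!all(dim(a) == dim(b))) stop("matrix dimensions differ")
    keep <- upper.tri(a, diag = TRUE)
    a <- a[keep]; b <- b[keep]
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("profiles not aligned")
  rmse <- sqrt(mean((a - b)^2))
  r <- if (stats::var(a) < 1e-15 || stats::var(b) < 1e-15) {
    warning("zero variance: Pearson r undefined")
    NA_real_
  } else stats::cor(a, b)
  comparison_stats(r, rmse, length(a))
}

#' Construct a ComparisonStats record
#' @param pearson_r Pearson correlation coefficient, or NA.
#' @param rmse root-mean-square error, >= 0, or NA.
#' @param n number of paired values.
#' @return object of class `comparison_stats`.
#' @export
comparison_stats <- function(pearson_r, rmse, n = NA_integer_) {
  if (!is.na(pearson_r) && abs(pearson_r) > 1 + 1e-12)
    stop("Pearson r outside [-1, 1]")
  if (!is.na(rmse) && rmse < 0) stop("RMSE must be >= 0")
  structure(list(pearson_r = pearson_r, rmse = rmse, n = n),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> r = %s, RMSE = %s (n = %s)\n",
              format(x$pearson_r, digits = 4), format(x$rmse, digits = 4),
              x$n))
  invisible(x)
}

#' Write an interaction profile as a tab-separated table
#'
#' @param profile an `interaction_profile`.
#' @param ens the fingerprinted ensemble (for residue pdb_numbers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, ens, path) {
  a <- ens$atoms
  pdb_num <- vapply(seq_len(n_residues(ens)),
                    function(r) a$pdb_number[a$res_index == r][1], 0L)
  tab <- data.frame(pdb_number = pdb_num, profile$populations,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
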