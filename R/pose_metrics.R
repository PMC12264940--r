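# Ligand pose RMSD metrics.
#
# frame-matched RMSD: docked pose vs the bound pose of the identical protein
# conformation (protein coordinates equal by construction, so no alignment
# is needed); best-matched RMSD: minimum ligand RMSD against every bound
# pose in the matching conformational cluster after Cα superposition.
# Both use heavy ligand atoms and plain atom-index correspondence (no
# symmetry correction).

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum_i ||R x_i + t - y_i||^2.
#'
#' @param mobile_coords,reference_coords n x 3 matrices, n >= 3,
#'   non-collinear.
#' @return list with `rotation` (3 x 3, det +1), `translation` (3-vector)
#'   and `rmsd` of the superposed points.
#' @export
superpose <- function(mobile_coords, reference_coords) {
  X <- matrix(mobile_coords, ncol = 3)
  Y <- matrix(reference_coords, ncol = 3)
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3) stop("need at least 3 points")
  xc <- colMeans(X); yc <- colMeans(Y)
  X0 <- sweep(X, 2, xc); Y0 <- sweep(Y, 2, yc)
  sv <- svd(crossprod(X0, Y0))
  if (sv$d[2] < 1e-10) stop("degenerate (collinear) point set")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- yc - as.vector(R %*% xc)
  fitted <- sweep(X %*% t(R), 2, t_vec, "+")
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform result of [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(matrix(coords, ncol = 3) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

# Plain heavy-atom RMSD between two ligand coordinate sets.
ligand_rmsd <- function(coords_a, coords_b, ligand) {
  ha <- ligand$atoms$is_heavy
  A <- matrix(coords_a, ncol = 3)
  B <- matrix(coords_b, ncol = 3)
  if (nrow(A) != length(ha) || nrow(B) != length(ha))
    stop("ligand atom-count mismatch")
  A <- A[ha, , drop = FALSE]
  B <- B[ha, , drop = FALSE]
  sqrt(mean(rowSums((A - B)^2)))
}

#' Frame-matched ligand RMSD
#'
#' RMSD over heavy ligand atoms between a docked pose and the bound pose of
#' the same protein conformation. Because the protein coordinates of the two
#' are identical by construction (holo docking re-uses the bound frames),
#' the alignment is the identity and the RMSD is computed directly.
#'
#' @param docked_pose a `pose`.
#' @param md_coords the bound-pose ligand coordinates of the same frame
#'   (n_atoms x 3, same atom ordering).
#' @param ligand the `ligand_model`.
#' @return RMSD in Å.
#' @export
frame_matched_rmsd <- function(docked_pose, md_coords, ligand) {
  ligand_rmsd(docked_pose$ligand_coords, md_coords, ligand)
}

#' Best-matched ligand RMSD within a conformational cluster
#'
#' For every bound frame of the cluster: superpose its Cα coordinates onto
#' the docked conformation's Cα, apply the transform to its ligand, and
#' compute the heavy-atom ligand RMSD to the docked pose. Returns the
#' minimum and the frame that achieves it.
#'
#' @param docked_pose a `pose`.
#' @param docked_conf the `conformation` the pose was docked onto.
#' @param cluster_holo a `holo_ensemble` restricted to the bound frames of
#'   the docked frame's cluster (or the full ensemble, if preferred).
#' @return list with `value` (Å), `matched_frame_id`, and `metric =
#'   "best_matched"`.
#' @export
best_matched_rmsd <- function(docked_pose, docked_conf, cluster_holo) {
  nf <- n_frames(cluster_holo$protein)
  if (nf == 0) stop("empty cluster")
  ca_d <- ca_rows(docked_conf)
  ref <- docked_conf$coords[ca_d, , drop = FALSE]
  ca_m <- ca_rows(cluster_holo$protein)
  best <- Inf; best_id <- NA
  for (i in seq_len(nf)) {
    tr <- superpose(cluster_holo$protein$coords[[i]][ca_m, , drop = FALSE],
                    ref)
    lig <- apply_transform(cluster_holo$ligand_coords[[i]], tr)
    v <- ligand_rmsd(docked_pose$ligand_coords, lig, cluster_holo$ligand)
    if (v < best) { best <- v; best_id <- cluster_holo$protein$frame_ids[[i]] }
  }
  list(value = best, matched_frame_id = best_id, metric = "best_matched")
}

#' Both RMSD metrics over a holo-docked ensemble
#'
#' Convenience driver for redocking runs: for every docked frame, the
#' frame-matched RMSD against its own bound pose and the best-matched RMSD
#' against its cluster's bound poses (all frames when `labels` is NULL).
#'
#' @param de a `docked_ensemble` produced by docking onto the bound frames
#'   of `holo`.
#' @param holo the `holo_ensemble` the frames came from.
#' @param labels optional per-frame cluster labels of `holo` frames.
#' @return data.frame with frame_id, frame_matched, best_matched,
#'   matched_frame_id.
#' @export
rmsd_table <- function(de, holo, labels = NULL) {
  kept <- setdiff(seq_len(n_frames(de$ensemble)), de$failed_frames)
  holo_ids <- unlist(holo$protein$frame_ids)
  rows <- lapply(seq_along(kept), function(k) {
    p <- de$selected[[k]]
    conf <- get_conformation(de$ensemble, kept[k])
    h <- match(p$frame_id, holo_ids)
    if (is.na(h)) stop("docked frame ", p$frame_id, " not in the holo ensemble")
    fm <- frame_matched_rmsd(p, holo$ligand_coords[[h]], de$ligand)
    members <- if (is.null(labels)) seq_len(n_frames(holo$protein)) else
      which(labels == labels[h])
    sub <- holo_ensemble(
      conformation_ensemble(holo$protein$atoms, holo$protein$coords[members],
                            frame_ids = holo$protein$frame_ids[members],
                            source_tag = holo$protein$source_tag),
      holo$ligand, holo$ligand_coords[members])
    bm <- best_matched_rmsd(p, conf, sub)
    data.frame(frame_id = p$frame_id, frame_matched = fm,
               best_matched = bm$value,
               matched_frame_id = bm$matched_frame_id)
  })
  do.call(rbind, rows)
}

#' Fractions of records below RMSD thresholds
#'
#' @param values RMSD values (Å).
#' @param thresholds Å thresholds (default 3 and 5); strict less-than.
#' @return named numeric vector of percentages (0-100 scale).
#' @export
threshold_fractions <- function(values, thresholds = c(3, 5)) {
  if (length(values) == 0) stop("no records")
  out <- vapply(thresholds, function(t) 100 * mean(values < t), 0)
  names(out) <- paste0("<", thresholds, "A")
  out
}

#' Format threshold fractions in the `a.bb (c.dd)` table convention
#'
#' Percentage below the first threshold with the second parenthesized.
#'
#' @param fractions output of [threshold_fractions()] (two thresholds).
#' @return character scalar, e.g. `"5.82 (10.70)"`.
#' @export
format_threshold_fractions <- function(fractions) {
  sprintf("%.2f (%.2f)", fractions[1], fractions[2])
}
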