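# Ensemble docking orchestration: bound-frame extraction, cluster-balanced
# sampling, per-residue and whole-conformation docking, best-pose selection.
#
# Apo, holo (redocking) and cross docking are the same computation on
# different inputs: docking always sees protein coordinates only. Holo
# docking strips the ligand from a ligand-bound ensemble first; cross
# docking docks ligand B onto protein frames from ligand A's holo ensemble.

#' Construct a ligand-bound (holo-style) ensemble
#'
#' Protein ensemble plus one set of ligand coordinates per frame, as produced
#' by a bound-state simulation or by [plant_bound_poses()].
#'
#' @param protein a `conf_ensemble`.
#' @param ligand a `ligand_model`.
#' @param ligand_coords list of n_ligand_atoms x 3 matrices, one per frame.
#' @return object of class `holo_ensemble`.
#' @export
holo_ensemble <- function(protein, ligand, ligand_coords) {
  if (length(ligand_coords) != n_frames(protein))
    stop("one ligand coordinate set required per frame")
  ligand_coords <- lapply(ligand_coords, function(x) {
    x <- matrix(as.numeric(x), ncol = 3)
    if (nrow(x) != nrow(ligand$atoms)) stop("ligand atom count mismatch")
    x
  })
  structure(list(protein = protein, ligand = ligand,
                 ligand_coords = ligand_coords),
            class = "holo_ensemble")
}

#' Bound-frame filter
#'
#' A frame is bound when at least one (heavy) protein atom is within `cutoff`
#' of at least one (heavy) ligand atom.
#'
#' @param cutoff distance cutoff in Å (default 6.0).
#' @param heavy_only use heavy atoms only (default TRUE).
#' @return object of class `bound_frame_filter`.
#' @export
bound_frame_filter <- function(cutoff = 6.0, heavy_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, heavy_only = heavy_only),
            class = "bound_frame_filter")
}

#' Extract ligand-bound frames from a holo ensemble
#'
#' Keeps frames whose minimum protein-ligand (heavy) atom distance is at most
#' the filter cutoff, strips the ligand, and reports the bound fraction
#' (kept / total) — the ensemble's simulation binding affinity proxy.
#'
#' @param holo a `holo_ensemble`.
#' @param filter a `bound_frame_filter`.
#' @return list with `ensemble` (protein-only `conf_ensemble` of the bound
#'   frames, original frame_ids preserved) and `bound_fraction`.
#' @export
extract_bound_frames <- function(holo, filter = bound_frame_filter()) {
  nf <- n_frames(holo$protein)
  if (nf == 0) stop("no frames")
  p_keep <- if (filter$heavy_only) holo$protein$atoms$is_heavy else
    rep(TRUE, nrow(holo$protein$atoms))
  l_keep <- if (filter$heavy_only) holo$ligand$atoms$is_heavy else
    rep(TRUE, nrow(holo$ligand$atoms))
  bound <- vapply(seq_len(nf), function(i) {
    d <- cross_dist(holo$protein$coords[[i]][p_keep, , drop = FALSE],
                    holo$ligand_coords[[i]][l_keep, , drop = FALSE])
    min(d) <= filter$cutoff
  }, TRUE)
  if (!any(bound)) {
    warning("no bound frames under the ", filter$cutoff, " Å cutoff")
    return(list(ensemble = NULL, bound_fraction = 0))
  }
  keep <- which(bound)
  ens <- conformation_ensemble(
    holo$protein$atoms, holo$protein$coords[keep],
    frame_ids = holo$protein$frame_ids[keep],
    source_tag = paste0("holo:", holo$ligand$name))
  list(ensemble = ens, bound_fraction = sum(bound) / nf)
}

#' Sample a fixed number of frames per cluster, without replacement
#'
#' @param ens a `conf_ensemble`.
#' @param labels per-frame cluster labels (same length as frames).
#' @param n_per_cluster frames to draw per cluster (default 1000); clusters
#'   with fewer frames contribute all of them, with a warning.
#' @param seed integer seed.
#' @return a `conf_ensemble` of the sampled frames (original frame_ids kept).
#' @export
sample_cluster_frames <- function(ens, labels, n_per_cluster = 1000, seed = 1L) {
  if (length(labels) != n_frames(ens))
    stop("labels must cover all frames")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  picked <- integer()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) == 0) { warning("empty cluster ", cl, ", skipped"); next }
    if (length(members) < n_per_cluster)
      warning("cluster ", cl, " has only ", length(members),
              " frames (< ", n_per_cluster, "); taking all")
    take <- if (length(members) <= n_per_cluster) members else
      sample(members, n_per_cluster)
    picked <- c(picked, sort(take))
  }
  conformation_ensemble(ens$atoms, ens$coords[picked],
                        frame_ids = ens$frame_ids[picked],
                        source_tag = ens$source_tag)
}

#' Per-residue ensemble docking
#'
#' For every conformation of the ensemble, one docking calculation is run per
#' residue, each restricted to a cubic box centered on that residue's center
#' of mass with edge `edge_scale * Rg(ligand)`. The best-scoring candidate
#' under the backend polarity becomes the frame's selected pose (ties broken
#' by lowest residue index), yielding one docked pose per conformation.
#'
#' @param ens a `conf_ensemble`.
#' @param ligand a `ligand_model`.
#' @param backend a `backend_spec` in boxed mode.
#' @param edge_scale box edge / Rg factor (default [DEFAULT_EDGE_SCALE]).
#' @param seed master seed; per-frame seeds are derived deterministically so
#'   serial and parallel schedules agree.
#' @param keep_candidates store every per-residue candidate pose (TRUE) or
#'   only their score table (still one pose object each; default TRUE).
#' @return a `docked_ensemble`.
#' @export
per_residue_ensemble_dock <- function(ens, ligand, backend = mock_backend(),
                                      edge_scale = DEFAULT_EDGE_SCALE,
                                      seed = 1L, keep_candidates = TRUE) {
  if (backend$mode != "boxed") stop("per-residue docking needs a boxed backend")
  rg <- radius_of_gyration(ligand)
  nf <- n_frames(ens)
  nr <- n_residues(ens)
  seeds <- derive_seeds(seed, nf)
  sgn <- if (backend$polarity == "lower_is_better") 1 else -1
  selected <- list()
  candidates <- vector("list", nf)
  failed_frames <- integer()
  for (i in seq_len(nf)) {
    conf <- get_conformation(ens, i)
    cands <- list()
    for (r in seq_len(nr)) {
      res <- tryCatch({
        box <- build_residue_box(conf, r, rg, edge_scale)
        ps <- backend_dock(backend, conf, ligand, box, n_poses = 1,
                           seed = seeds[i])
        p <- ps[[1]]
        p$origin_residue <- r
        p
      }, error = function(e) {
        if (inherits(e, "backend_unavailable")) stop(e)
        warning("frame ", conf$frame_id, " residue ", r,
                ": box failed (", conditionMessage(e), "), excluded")
        NULL
      })
      if (!is.null(res)) cands[[length(cands) + 1]] <- res
    }
    candidates[[i]] <- cands
    if (length(cands) == 0) {
      warning("frame ", conf$frame_id,
              ": all residue boxes failed; frame excluded")
      failed_frames <- c(failed_frames, i)
      next
    }
    scores <- vapply(cands, function(p) p$raw_score, 0)
    origins <- vapply(cands, function(p) p$origin_residue, 0L)
    best <- which(sgn * scores == min(sgn * scores))
    best <- best[which.min(origins[best])]  # tie: lowest residue index
    selected[[length(selected) + 1]] <- cands[[best]]
  }
  docked_ensemble(ens, ligand, selected, candidates,
                  backend_tag = backend$name, polarity = backend$polarity,
                  failed_frames = failed_frames)
}

#' Whole-conformation ensemble docking
#'
#' One docking calculation per conformation with no per-residue restriction
#' of the search space; the backend returns `n_poses` candidates per frame
#' and the best under the declared polarity is selected (DiffDock-style
#' engines rank by confidence, higher is better).
#'
#' @inheritParams per_residue_ensemble_dock
#' @param n_poses candidate poses requested per conformation (default 10).
#' @return a `docked_ensemble` with one selected pose per frame;
#'   `origin_residue` is NA throughout.
#' @export
whole_conformation_ensemble_dock <- function(ens, ligand,
                                             backend = mock_backend(),
                                             n_poses = 10, seed = 1L) {
  nf <- n_frames(ens)
  seeds <- derive_seeds(seed, nf)
  sgn <- if (backend$polarity == "lower_is_better") 1 else -1
  selected <- list()
  candidates <- vector("list", nf)
  failed_frames <- integer()
  for (i in seq_len(nf)) {
    conf <- get_conformation(ens, i)
    cands <- tryCatch(
      backend_dock(backend, conf, ligand, box = NULL, n_poses = n_poses,
                   seed = seeds[i]),
      error = function(e) {
        if (inherits(e, "backend_unavailable")) stop(e)
        warning("frame ", conf$frame_id, ": docking failed (",
                conditionMessage(e), "); frame excluded")
        list()
      })
    candidates[[i]] <- cands
    if (length(cands) == 0) { failed_frames <- c(failed_frames, i); next }
    scores <- vapply(cands, function(p) p$raw_score, 0)
    selected[[length(selected) + 1]] <- cands[[which.min(sgn * scores)]]
  }
  docked_ensemble(ens, ligand, selected, candidates,
                  backend_tag = backend$name, polarity = backend$polarity,
                  failed_frames = failed_frames)
}
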