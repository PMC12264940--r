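# Conformational clustering: pairwise-Ca-distance features, 2-D t-SNE
# embedding with silhouette-driven perplexity selection, k-means
# partitioning, bend-angle summaries and cluster-population weighting.

#' Featurize an ensemble as pairwise Cα–Cα distances
#'
#' One row per frame, n(n-1)/2 columns (all unordered Cα pairs). Pairwise
#' distances are invariant under rigid motion, so identical conformations in
#' different lab frames featurize identically.
#'
#' @param ens a `conf_ensemble` whose residues all carry a Cα.
#' @return numeric matrix, n_frames x n(n-1)/2.
#' @export
featurize_ensemble <- function(ens) {
  if (n_residues(ens) < 4) stop("need at least 4 residues to featurize")
  ca <- ca_rows(ens)
  t(vapply(ens$coords, function(m) as.vector(stats::dist(m[ca, , drop = FALSE])),
           numeric(length(ca) * (length(ca) - 1) / 2)))
}

#' Cluster an ensemble via t-SNE + k-means with perplexity selection
#'
#' For every perplexity on the grid: a 2-D t-SNE embedding of the feature
#' matrix, k-means with `k` clusters on the embedding, and the mean
#' silhouette width computed in embedding space. The perplexity with the
#' highest silhouette wins; its labels and embedding are returned. The whole
#' procedure is deterministic given `seed`.
#'
#' @param features frame x feature matrix (see [featurize_ensemble()]).
#' @param k number of clusters (default 20).
#' @param perplexity_grid candidate perplexities; each must be below
#'   (n_frames - 1) / 3.
#' @param seed integer seed.
#' @param max_iter t-SNE iterations (default 500).
#' @return object of class `cluster_model`: labels (0..k-1), k, embedding,
#'   chosen_perplexity, silhouette_by_perplexity, populations.
#' @export
cluster_ensemble <- function(features, k = 20, perplexity_grid = c(30, 50),
                             seed = 1L, max_iter = 500) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer frames (", n, ") than clusters (", k, ")")
  if (length(perplexity_grid) == 0) stop("empty perplexity grid")
  if (any(perplexity_grid >= n)) stop("perplexity must be < n_frames")
  if (all(apply(features, 2, stats::var) < 1e-12))
    stop("zero-variance features")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best <- NULL
  sil_tab <- data.frame(perplexity = numeric(), silhouette = numeric())
  for (p in perplexity_grid) {
    set.seed(as.integer(seed))
    emb <- Rtsne::Rtsne(features, dims = 2, perplexity = p,
                        max_iter = max_iter, check_duplicates = FALSE,
                        pca = FALSE, verbose = FALSE)$Y
    set.seed(as.integer(seed))
    km <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
    sil <- mean(cluster::silhouette(km$cluster, stats::dist(emb))[, 3])
    sil_tab <- rbind(sil_tab, data.frame(perplexity = p, silhouette = sil))
    if (is.null(best) || sil > best$sil) {
      best <- list(perplexity = p, sil = sil, emb = emb,
                   labels = km$cluster - 1L)
    }
  }
  pops <- as.numeric(table(factor(best$labels, levels = 0:(k - 1)))) / n
  structure(
    list(labels = best$labels, k = as.integer(k), embedding = best$emb,
         chosen_perplexity = best$perplexity,
         silhouette_by_perplexity = sil_tab, populations = pops),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_model> %d frames in %d clusters (perplexity %g, silhouette %.3f)\n",
    length(x$labels), x$k, x$chosen_perplexity,
    max(x$silhouette_by_perplexity$silhouette)))
  invisible(x)
}

#' Bend angle of a conformation
#'
#' Interior angle (degrees) at the middle Cα of three designated residues — a
#' compactness descriptor of a disordered chain (small angle = bent/compact,
#' near 180° = extended). Default anchors are the first, middle and last
#' residues of the chain.
#'
#' @param conf a `conformation`.
#' @param first_res,middle_res,last_res residue indices of the three anchors.
#' @return angle in degrees, in [0, 180].
#' @export
bend_angle <- function(conf,
                       first_res = 1L,
                       middle_res = (n_residues(conf) + 1L) %/% 2L,
                       last_res = n_residues(conf)) {
  ca_of <- function(r) {
    rows <- residue_atom_rows(conf, r)
    ca <- rows[conf$atoms$atom_name[rows] == "CA"]
    if (length(ca) != 1) stop("residue ", r, " lacks a CA atom")
    conf$coords[ca, ]
  }
  angle_deg(ca_of(first_res), ca_of(middle_res), ca_of(last_res))
}

#' Population-weighted average of per-cluster values
#'
#' Weights the average value of an ensemble property over clusters by each
#' cluster's population in the full source ensemble.
#'
#' @param values named (or ordered) numeric vector, one value per cluster.
#' @param populations per-cluster fractions, summing to 1; names, if present,
#'   must match `values`.
#' @return the weighted average.
#' @export
cluster_weighted_average <- function(values, populations) {
  if (length(values) != length(populations))
    stop("values and populations differ in length")
  if (!is.null(names(values)) && !is.null(names(populations))) {
    if (!setequal(names(values), names(populations)))
      stop("mismatched cluster ids")
    populations <- populations[names(values)]
  }
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1")
  sum(values * populations)
}

#' Per-cluster summaries: size, mean bend angle, mean normalized score
#'
#' @param ens a `conf_ensemble`.
#' @param labels per-frame cluster labels (0-based).
#' @param normalized_scores optional per-frame normalized docking scores.
#' @param anchors residue indices (first, middle, last) for the bend angle.
#' @return data.frame with cluster_id, n_frames, mean_bend_angle and (when
#'   scores are given) mean_normalized_score.
#' @export
cluster_summaries <- function(ens, labels, normalized_scores = NULL,
                              anchors = NULL) {
  if (length(labels) != n_frames(ens)) stop("labels must cover all frames")
  if (is.null(anchors))
    anchors <- c(1L, (n_residues(ens) + 1L) %/% 2L, n_residues(ens))
  angles <- vapply(seq_len(n_frames(ens)), function(i) {
    bend_angle(get_conformation(ens, i), anchors[1], anchors[2], anchors[3])
  }, 0)
  ids <- sort(unique(labels))
  out <- data.frame(
    cluster_id = ids,
    n_frames = vapply(ids, function(c) sum(labels == c), 0L),
    mean_bend_angle = vapply(ids, function(c) mean(angles[labels == c]), 0)
  )
  if (!is.null(normalized_scores)) {
    if (length(normalized_scores) != length(labels))
      stop("normalized_scores must cover all frames")
    out$mean_normalized_score <-
      vapply(ids, function(c) mean(normalized_scores[labels == c]), 0)
  }
  out
}

#' Write a cluster model as a labels table plus structured metadata
#'
#' @param cm a `cluster_model`.
#' @param ens the clustered `conf_ensemble` (for frame_ids).
#' @param prefix output path prefix: writes `<prefix>_labels.tsv` and
#'   `<prefix>_meta.json`.
#' @return the two paths, invisibly.
#' @export
write_cluster_model <- function(cm, ens, prefix) {
  lab_path <- paste0(prefix, "_labels.tsv")
  utils::write.table(
    data.frame(frame_id = unlist(ens$frame_ids), cluster = cm$labels),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(k = cm$k, chosen_perplexity = cm$chosen_perplexity,
         silhouette_by_perplexity = cm$silhouette_by_perplexity,
         populations = cm$populations),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(labels = lab_path, meta = meta_path))
}
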