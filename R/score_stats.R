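# Docking-score statistics: joint min-max normalization, bootstrap
# uncertainties, relative-affinity ranking, and score-structure
# correlations.
#
# One normalization scale is fitted per docking method across the pooled
# scores of ALL ligands compared, so normalized scores are comparable
# between ligands: the most favorable pooled score maps to 1, the least
# favorable to 0.

#' Fit a joint min-max normalization scale
#'
#' @param all_scores raw scores pooled across every ligand docked with one
#'   method.
#' @param polarity `"lower_is_better"` or `"higher_is_better"`.
#' @param method_tag free-text tag carried onto score tables.
#' @return object of class `normalization_scale` with `x_min` (worst score),
#'   `x_max` (best score), `polarity`, `method_tag`.
#' @export
fit_normalization <- function(all_scores, polarity = "lower_is_better",
                              method_tag = "default") {
  polarity <- match.arg(polarity, c("lower_is_better", "higher_is_better"))
  all_scores <- as.numeric(all_scores)
  if (length(unique(all_scores)) < 2)
    stop("need at least two distinct scores to fit a scale")
  if (polarity == "lower_is_better") {
    x_max <- min(all_scores); x_min <- max(all_scores)
  } else {
    x_max <- max(all_scores); x_min <- min(all_scores)
  }
  structure(list(x_min = x_min, x_max = x_max, polarity = polarity,
                 method_tag = method_tag),
            class = "normalization_scale")
}

#' Min-max normalize raw docking scores
#'
#' `x_scaled = (x - x_min) / (x_max - x_min)`: the best observed score maps
#' to 1, the worst to 0, linearly in between. Values outside the fitted
#' range are clipped to [0, 1] with a warning.
#'
#' @param x raw scores.
#' @param scale a `normalization_scale`.
#' @return normalized scores in [0, 1].
#' @export
normalize_scores <- function(x, scale) {
  if (abs(scale$x_max - scale$x_min) < 1e-300) stop("degenerate scale")
  z <- (x - scale$x_min) / (scale$x_max - scale$x_min)
  if (any(z < -1e-12 | z > 1 + 1e-12)) {
    warning("scores outside the fitted range were clipped to [0, 1]")
    z <- pmin(pmax(z, 0), 1)
  }
  pmin(pmax(z, 0), 1) + 0  # + 0 folds IEEE -0 into +0
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the values with replacement `n_boot` times; the CI is the
#' 2.5/97.5 percentile of the resampled means and the reported error is the
#' mean of the upper and lower deviations of that 95% interval.
#'
#' @param values numeric sample.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed (deterministic output).
#' @param conf confidence level (default 0.95).
#' @return list with `mean`, `ci_low`, `ci_high`, `error`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 10000, seed = 1L,
                              conf = 0.95) {
  if (length(values) == 0) stop("empty sample")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(values)
  means <- vapply(seq_len(n_boot), function(b) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  m <- mean(values)
  list(mean = m, ci_low = ci[1], ci_high = ci[2],
       error = ((m - ci[1]) + (ci[2] - m)) / 2)
}

#' Relative-affinity table across ligands
#'
#' Mean normalized score per ligand (cluster-weighted when labels and
#' cluster populations are given, plain mean otherwise), percentile
#' bootstrap error, relative affinity scaled so the tightest binder is 1.0,
#' and rank.
#'
#' @param normalized_scores named list: per ligand, the vector of normalized
#'   selected-pose scores (one common scale already applied).
#' @param labels optional named list of per-frame cluster labels aligned
#'   with each ligand's scores.
#' @param populations optional per-cluster source-ensemble weights (summing
#'   to 1, ordered by sorted cluster id), recycled across ligands.
#' @param n_boot,seed bootstrap settings.
#' @param cross_docked logical: annotates the table when scores derive from
#'   mismatched holo ensembles, where affinity comparison is unreliable.
#' @return data.frame (class `affinity_table`) with ligand, mean_score,
#'   error, relative_affinity, rank.
#' @export
affinity_table <- function(normalized_scores, labels = NULL,
                           populations = NULL, n_boot = 10000, seed = 1L,
                           cross_docked = FALSE) {
  keep <- vapply(normalized_scores, length, 0L) > 0
  if (!all(keep)) {
    warning("ligand(s) with no scores excluded: ",
            paste(names(normalized_scores)[!keep], collapse = ", "))
    normalized_scores <- normalized_scores[keep]
  }
  if (length(normalized_scores) == 0) stop("no scores at all")
  means <- vapply(names(normalized_scores), function(tag) {
    x <- normalized_scores[[tag]]
    if (!is.null(labels) && !is.null(populations)) {
      lab <- labels[[tag]]
      ids <- sort(unique(lab))
      per_cluster <- vapply(ids, function(c) mean(x[lab == c]), 0)
      cluster_weighted_average(per_cluster, populations[ids + 1])
    } else mean(x)
  }, 0)
  errs <- vapply(seq_along(normalized_scores), function(k) {
    bootstrap_mean_ci(normalized_scores[[k]], n_boot,
                      seed = seed + k - 1L)$error
  }, 0)
  rel <- means / max(means)
  out <- data.frame(ligand = names(normalized_scores),
                    mean_score = unname(means), error = errs,
                    relative_affinity = unname(rel),
                    rank = rank(-means, ties.method = "first"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "cross_docked") <- cross_docked
  if (cross_docked)
    attr(out, "caveat") <-
      "cross-docked scores: relative affinities may be unreliable"
  class(out) <- c("affinity_table", "data.frame")
  out
}

#' @export
print.affinity_table <- function(x, ...) {
  NextMethod()
  if (isTRUE(attr(x, "cross_docked")))
    cat("NOTE:", attr(x, "caveat"), "\n")
  invisible(x)
}

#' Probability that a uniformly random ranking is exactly correct
#'
#' With n ligands there are n! strict orderings, so a random ordering
#' matches the reference with probability 1/n! (one in six for three
#' ligands).
#'
#' @param n_ligands number of ligands ranked.
#' @return 1 / n!.
#' @export
ranking_null_probability <- function(n_ligands) {
  if (n_ligands < 1) stop("need at least one ligand")
  1 / factorial(n_ligands)
}

#' Correlation between cluster bend angle and normalized docking score
#'
#' Pearson r between per-cluster mean bend angles and per-cluster mean
#' normalized scores. The two quantities carry different units, so no RMSE
#' is defined for this comparison (returned as NA).
#'
#' @param summaries data.frame from [cluster_summaries()] with columns
#'   mean_bend_angle and mean_normalized_score.
#' @return a `comparison_stats` (rmse = NA).
#' @export
score_structure_correlation <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 clusters")
  a <- summaries$mean_bend_angle
  s <- summaries$mean_normalized_score
  if (stats::var(a) < 1e-15 || stats::var(s) < 1e-15) {
    warning("zero variance: Pearson r undefined")
    return(comparison_stats(NA_real_, NA_real_, nrow(summaries)))
  }
  comparison_stats(stats::cor(a, s), NA_real_, nrow(summaries))
}

#' Write an affinity table as tab-separated text
#'
#' @param tab an `affinity_table`.
#' @param path output file; the method tag and any cross-docking caveat are
#'   written as `#` comment lines.
#' @param method_tag normalization-scale tag to record.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(tab, path, method_tag = "default") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", method_tag), con)
  if (isTRUE(attr(tab, "cross_docked")))
    writeLines(paste0("# ", attr(tab, "caveat")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
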