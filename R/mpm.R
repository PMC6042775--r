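# Core profile-map statistics: bootstrapped centers, Mahalanobis distances,
# chi-square score mapping, grand scores, internal consistency, projection.

#' Fit a psychological center model for one cluster
#'
#' The cluster's center is the bootstrap estimate of the multivariate mean
#' of the author's documents: the average, over `B` resamples of the rows
#' (with replacement, resample size = number of documents), of the resample
#' mean. The covariance is the ordinary sample covariance (n - 1
#' denominator) of the original rows, optionally ridge-stabilised by adding
#' `ridge * mean(diag(cov))` to the diagonal.
#'
#' @param cluster_matrix Documents-by-variables numeric matrix (at least 3
#'   rows).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional seed; the fit is deterministic given the seed.
#' @param ridge Ridge coefficient for the covariance diagonal (default 0).
#' @return An object of class `mpm_center`: list with `center`, `cov`,
#'   `n_docs`, `B`, `seed`, `variables`, `ridge`.
#' @export
fit_center_model <- function(cluster_matrix, B = 1000, seed = NULL,
                             ridge = 0) {
  X <- as.matrix(cluster_matrix)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) {
    stop("at least 3 documents are required to fit a center model (got ",
         n, ")", call. = FALSE)
  }
  stopifnot(B >= 1, ridge >= 0)
  center <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    groups <- rep(seq_len(B), each = n)
    resample_means <- rowsum(X[idx, , drop = FALSE], groups) / n
    colMeans(resample_means)
  })
  names(center) <- colnames(X)
  S <- stats::cov(X)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), p)
  structure(
    list(center = center, cov = S, n_docs = n, B = as.integer(B),
         seed = seed, variables = colnames(X), ridge = ridge),
    class = "mpm_center"
  )
}

#' Map squared Mahalanobis distances to 0-100 typicality scores
#'
#' The score is `100 * P(chi-square_df > d2)`: 100 at the center, falling
#' strictly towards 0 as the squared distance grows, with degrees of
#' freedom equal to the cluster dimensionality. Under multivariate normal
#' sampling a document drawn from the author's own distribution scores
#' approximately uniformly on (0, 100).
#'
#' @param d2 Non-negative squared Mahalanobis distances.
#' @param df Cluster dimensionality (number of member variables).
#' @return Scores in `[0, 100]`.
#' @examples
#' chisq_score(0, df = 4)        # at the center: 100
#' chisq_score(3.841, df = 1)    # 95th percentile of chi-square(1): 5.00
#' @export
chisq_score <- function(d2, df) {
  stopifnot(df >= 1)
  if (any(d2 < 0)) {
    warning("negative squared distance(s) clamped to 0", call. = FALSE)
    d2 <- pmax(d2, 0)
  }
  100 * stats::pchisq(d2, df = df, lower.tail = FALSE)
}

#' Distance profiles of documents from the cluster centers
#'
#' For every document and cluster, computes the squared Mahalanobis
#' distance `d2 = (x - center)' pinv(cov) (x - center)` using the
#' Moore-Penrose pseudo-inverse of the model covariance, and the
#' corresponding [chisq_score()]. With an identity covariance `d2` reduces
#' to the squared Euclidean distance.
#'
#' @param cluster_matrices Named list of documents-by-variables matrices
#'   (see [build_cluster_matrices()]); all must share the document order.
#' @param center_models Named list of `mpm_center` models over the same
#'   clusters and variable order.
#' @return An object of class `mpm_profiles`: list with `scores` and `d2`,
#'   both documents-by-clusters matrices (row names = doc ids).
#' @export
distance_scores <- function(cluster_matrices, center_models) {
  if (!setequal(names(cluster_matrices), names(center_models))) {
    stop("cluster matrices and center models name different clusters",
         call. = FALSE)
  }
  cl_names <- names(cluster_matrices)
  n <- nrow(cluster_matrices[[1]])
  d2 <- matrix(NA_real_, n, length(cl_names),
               dimnames = list(rownames(cluster_matrices[[1]]), cl_names))
  scores <- d2
  for (cl in cl_names) {
    X <- cluster_matrices[[cl]]
    model <- center_models[[cl]]
    if (!identical(colnames(X), model$variables)) {
      stop("variable mismatch in cluster '", cl, "': matrix has [",
           paste(colnames(X), collapse = ", "), "], model has [",
           paste(model$variables, collapse = ", "), "]", call. = FALSE)
    }
    P <- pinv_sym(model$cov)
    Xc <- sweep(X, 2, model$center)
    v <- rowSums((Xc %*% P) * Xc)
    if (any(v < 0)) {
      warning("negative squared distance(s) in cluster '", cl,
              "' clamped to 0", call. = FALSE)
      v <- pmax(v, 0)
    }
    d2[, cl] <- v
    scores[, cl] <- chisq_score(v, df = ncol(X))
  }
  structure(list(scores = scores, d2 = d2), class = "mpm_profiles")
}

#' Grand profile score: the median of the cluster scores
#'
#' With the default 13-cluster scheme this is the 7th order statistic of a
#' document's 13 scores; schemes with an even number of clusters use the
#' midpoint of the two central values. The median (rather than the mean) is
#' used so that one or two superficially extreme clusters cannot dominate
#' the aggregate.
#'
#' @param scores A numeric vector of per-cluster scores, or a matrix / data
#'   frame of them (documents in rows).
#' @return A single median, or one per row.
#' @examples
#' grand_score(c(10, 50, 90))
#' @export
grand_score <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.matrix(scores)) {
    return(apply(scores, 1, grand_score))
  }
  if (anyNA(scores)) {
    bad <- names(scores)[is.na(scores)]
    if (is.null(bad)) bad <- which(is.na(scores))
    stop("missing cluster score(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::median(scores)
}

#' Internal consistency of the cluster distance scores
#'
#' Treats the per-cluster scores as items of a scale and computes raw
#' (covariance-based) Cronbach's alpha,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`,
#' together with the standardized (correlation-based) variant, the Pearson
#' correlation between per-document mean and median scores, and the full
#' item inter-correlation matrix.
#'
#' @param score_matrix Documents-by-clusters score matrix (>= 3 rows).
#' @return An object of class `mpm_consistency`: list with `alpha`,
#'   `alpha_std`, `mean_median_r`, `item_correlations`, `k`, `n`.
#' @export
internal_consistency <- function(score_matrix) {
  S <- as.matrix(score_matrix)
  n <- nrow(S)
  k <- ncol(S)
  if (n < 3) stop("at least 3 documents required", call. = FALSE)
  total_var <- stats::var(rowSums(S))
  if (total_var <= 0) {
    stop("total score variance is zero; alpha is undefined", call. = FALSE)
  }
  item_var <- apply(S, 2, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  R <- suppressWarnings(stats::cor(S))
  rbar <- mean(R[lower.tri(R)], na.rm = TRUE)
  alpha_std <- k * rbar / (1 + (k - 1) * rbar)
  mmr <- stats::cor(rowMeans(S), apply(S, 1, stats::median))
  structure(
    list(alpha = alpha, alpha_std = alpha_std, mean_median_r = mmr,
         item_correlations = R, k = k, n = n),
    class = "mpm_consistency"
  )
}

#' @export
print.mpm_consistency <- function(x, ...) {
  cat(sprintf(
    "<mpm_consistency> n = %d documents, k = %d items\n  raw alpha = %.3f, standardized alpha = %.3f, mean-median r = %.3f\n",
    x$n, x$k, x$alpha, x$alpha_std, x$mean_median_r))
  invisible(x)
}

#' Project cluster scores to two map dimensions
#'
#' Column-standardized principal components analysis of the score matrix;
#' the first two component scores give each document's position on the 2-D
#' profile map. Signs are fixed so the largest-magnitude loading of each
#' component is positive. The projection is a visual aid only: distances on
#' the map are approximate.
#'
#' @param score_matrix Documents-by-clusters score matrix (>= 3 rows).
#' @return A two-column matrix (`pc1`, `pc2`), one row per document, with
#'   the explained variance proportions in attribute `"explained"`.
#' @export
project_map <- function(score_matrix) {
  S <- as.matrix(score_matrix)
  if (nrow(S) < 3) stop("at least 3 documents required", call. = FALSE)
  sds <- apply(S, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) {
    stop("fewer than 2 clusters with non-zero variance; cannot project",
         call. = FALSE)
  }
  Z <- scale(S[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (ncol(pc$x) < 2) stop("rank below 2; cannot project", call. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("pc1", "pc2")
  rownames(coords) <- rownames(S)
  attr(coords, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  coords
}

#' List clusters on which a document is highly discrepant
#'
#' Decomposes a profile by flagging the clusters whose typicality score is
#' at or below `threshold` (default 20), in scheme order. These are the
#' processes along which the document sits unusually far from the author's
#' center and are the natural starting point for interpretation.
#'
#' @param scores Named numeric vector of per-cluster scores for one
#'   document.
#' @param threshold Score cutoff (default 20).
#' @return Character vector of discrepant cluster names (possibly empty).
#' @export
decompose_profile <- function(scores, threshold = 20) {
  stopifnot(is.numeric(scores))
  names(scores)[scores <= threshold]
}

#' Run the full profile-map analysis on a feature table
#'
#' Builds the per-cluster matrices, fits a bootstrapped center model per
#' cluster, computes distance scores and grand (median) scores, projects
#' the score matrix to two map dimensions and assesses internal
#' consistency. Every document in `features` contributes to the centers and
#' covariances ("leave-in"): a questioned work inserted into the table is
#' scored inside the map it helped define, mirroring how an investigator
#' would treat a work provisionally attributed to the candidate.
#'
#' @param features Feature table (documents in rows; see [score_corpus()]).
#' @param scheme Cluster scheme (default [default_cluster_scheme()]).
#' @param B Bootstrap resamples per cluster center (default 1000).
#' @param seed Optional seed; results are deterministic given the seed.
#' @param ridge Ridge coefficient passed to [fit_center_model()].
#' @return An object of class `mpm_map`: list with
#'   `profiles` (data frame: `doc_id`, `author` if present, one column per
#'   cluster score, `grand_score`, `pc1`, `pc2`), `d2`, `models`,
#'   `consistency`, `scheme`, `B`, `seed`.
#' @examples
#' tab <- load_table7_fixture()
#' scores <- as.matrix(tab[, cluster_names()])
#' grand_score(scores[1, ])
#' @export
mpm_analyze <- function(features, scheme = default_cluster_scheme(),
                        B = 1000, seed = NULL, ridge = 0) {
  if (anyDuplicated(features$doc_id)) {
    stop("duplicate doc_id in feature table", call. = FALSE)
  }
  mats <- build_cluster_matrices(features, scheme)
  scheme_used <- attr(mats, "scheme")
  seeds <- derive_seeds(seed, length(mats))
  models <- Map(function(X, s) fit_center_model(X, B = B, seed = s,
                                                ridge = ridge),
                mats, seeds)
  prof <- distance_scores(mats, models)
  grand <- grand_score(prof$scores)
  coords <- project_map(prof$scores)
  cons <- internal_consistency(prof$scores)
  out <- data.frame(doc_id = features$doc_id, stringsAsFactors = FALSE)
  if ("author" %in% names(features)) out$author <- features$author
  out <- cbind(out, as.data.frame(prof$scores))
  out$grand_score <- unname(grand)
  out$pc1 <- unname(coords[, "pc1"])
  out$pc2 <- unname(coords[, "pc2"])
  structure(
    list(profiles = out, d2 = prof$d2, models = models,
         consistency = cons, scheme = scheme_used, B = as.integer(B),
         seed = seed),
    class = "mpm_map"
  )
}

#' @export
print.mpm_map <- function(x, ...) {
  cat("<mpm_map>", nrow(x$profiles), "documents,", length(x$scheme),
      "clusters, B =", x$B, "\n")
  ord <- order(-x$profiles$grand_score)
  show <- x$profiles[ord, c("doc_id", "grand_score")]
  print(utils::head(show, 10), row.names = FALSE)
  if (nrow(show) > 10) cat("  ...\n")
  cat(sprintf("raw alpha = %.3f\n", x$consistency$alpha))
  invisible(x)
}

#' @param x An `mpm_map` object.
#' @param highlight Optional character vector of doc ids drawn as filled
#'   red points (e.g. inserted or questioned works).
#' @param ... Passed to [graphics::plot()].
#' @describeIn mpm_analyze Scatter of the 2-D profile map; the origin area
#'   marks the psychological center.
#' @export
plot.mpm_map <- function(x, highlight = NULL, ...) {
  p <- x$profiles
  graphics::plot(p$pc1, p$pc2, xlab = "map dimension 1",
                 ylab = "map dimension 2", pch = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (!is.null(highlight)) {
    sel <- p$doc_id %in% highlight
    graphics::points(p$pc1[sel], p$pc2[sel], pch = 19, col = "red")
  }
  invisible(x)
}

#' Write an analysed map's profiles to CSV
#'
#' @param map An `mpm_map`.
#' @param path Output CSV path.
#' @export
write_profiles <- function(map, path) {
  stopifnot(inherits(map, "mpm_map"))
  utils::write.csv(map$profiles, path, row.names = FALSE)
  invisible(path)
}
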