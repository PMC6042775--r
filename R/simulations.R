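# Simulation utilities: detection power of the insertion analysis and the
# null calibration of the chi-square score mapping.

#' Detection power of the insertion analysis under a known offset
#'
#' Repeatedly generates a synthetic single-author corpus, inserts a
#' candidate whose feature vector is offset from the author's center by
#' `offset_sd` within-author standard deviations on every variable, and
#' records how often the insertion lands at rank 1 (the lowest grand score
#' in the map). At offset 0 the candidate is just another document of the
#' author; power should grow monotonically with the offset.
#'
#' @param offset_sd Center offset, in units of the within-author SD.
#' @param n_runs Number of seeded simulation runs (default 100).
#' @param n_base Verified works in the base corpus (default 16).
#' @param variables Feature variables (default [default_variables()]).
#' @param within_sd Within-author document SD (default 2.5).
#' @param B Bootstrap resamples per center (default 1000).
#' @param seed Optional seed.
#' @return List with `recovery_rate` (proportion of runs at rank 1),
#'   `ranks` (integer vector) and `n_runs`.
#' @export
insertion_power <- function(offset_sd, n_runs = 100, n_base = 16,
                            variables = default_variables(),
                            within_sd = 2.5, B = 1000, seed = NULL) {
  scheme <- reduced_default_scheme()
  seeds <- derive_seeds(seed, n_runs)
  ranks <- vapply(seeds, function(s) {
    ss <- derive_seeds(s, 3)
    mu <- with_seed(ss[[1]], {
      m <- pmin(pmax(stats::rnorm(length(variables), 50, 2 * within_sd),
                     0), 100)
      names(m) <- variables
      m
    })
    prof <- author_profile("base", mu, cov = within_sd)
    base <- gen_author_feature_table(list(prof), n_base, seed = ss[[2]])
    cand <- base[1, , drop = FALSE]
    cand$doc_id <- "questioned"
    cand[, variables] <- pmin(pmax(mu + offset_sd * within_sd, 0), 100)
    run <- insert_and_score(base, cand, scheme = scheme, B = B,
                            seed = ss[[3]])
    run$inserted_rank
  }, integer(1))
  list(recovery_rate = mean(ranks == 1L), ranks = ranks, n_runs = n_runs)
}

# Default scheme without the proprietary summary variables (Complexity
# keeps only Sixltr and is dropped; Style is dropped entirely).
reduced_default_scheme <- function() {
  full <- unclass(default_cluster_scheme())
  red <- lapply(full, setdiff, y = SUMMARY_VARIABLES)
  cluster_scheme(red[lengths(red) >= 2])
}

#' Null calibration of the per-cluster typicality scores
#'
#' Draws a large single-author corpus from one multivariate normal per
#' cluster, runs the profile-map scoring on it, and Kolmogorov-Smirnov
#' tests each cluster's scores against the uniform distribution on
#' (0, 100). When the chi-square mapping is correctly calibrated, scores of
#' documents that truly belong to the author are approximately uniform, so
#' none of the tests should reject at small significance levels.
#'
#' @param n_docs Documents to draw (default 500).
#' @param variables Feature variables (default [default_variables()]).
#' @param within_sd Within-author SD (default 2.5).
#' @param B Bootstrap resamples per center (default 1000).
#' @param seed Optional seed.
#' @return List with `p_values` (named per cluster), `min_p`, `n_docs`.
#' @export
null_score_uniformity <- function(n_docs = 500,
                                  variables = default_variables(),
                                  within_sd = 2.5, B = 1000, seed = NULL) {
  scheme <- reduced_default_scheme()
  ss <- derive_seeds(seed, 3)
  mu <- with_seed(ss[[1]], {
    m <- pmin(pmax(stats::rnorm(length(variables), 50, 2 * within_sd),
                   0), 100)
    names(m) <- variables
    m
  })
  prof <- author_profile("null_author", mu, cov = within_sd)
  tab <- gen_author_feature_table(list(prof), n_docs, seed = ss[[2]])
  map <- mpm_analyze(tab, scheme = scheme, B = B, seed = ss[[3]])
  S <- as.matrix(map$profiles[, names(scheme)])
  p <- apply(S, 2, function(x) {
    suppressWarnings(stats::ks.test(x / 100, "punif"))$p.value
  })
  list(p_values = p, min_p = min(p), n_docs = n_docs)
}

#' Separation of same- and different-author degradation curves
#'
#' For each of `n_runs` seeds, generates a small synthetic corpus and
#' builds one same-author curve (two halves of one author's segments,
#' differing only in superficial per-work offsets) and one
#' different-author curve (segments of two distinct authors), then checks
#' whether the same-author curve degrades more from the first to the last
#' iteration. This is the core premise of unmasking.
#'
#' @param n_runs Number of seeded runs (default 50).
#' @param config An [unmasking_config()].
#' @param segments_per_work Segments per work (default 8).
#' @param seed Optional seed.
#' @return List with `separation_rate` (proportion of runs where the
#'   same-author drop exceeds the different-author drop), `drops` (two-
#'   column matrix) and `n_runs`.
#' @export
unmasking_separation <- function(n_runs = 50, config = unmasking_config(),
                                 segments_per_work = 8, seed = NULL) {
  seeds <- derive_seeds(seed, n_runs)
  drops <- t(vapply(seeds, function(s) {
    ss <- derive_seeds(s, 3)
    corpus <- gen_segment_corpus(n_authors = 2, works_per_author = 4,
                                 segments_per_work = segments_per_work,
                                 seed = ss[[1]])
    m <- feature_matrix(corpus)
    a1 <- corpus$author == "author01"
    works1 <- unique(corpus$doc[a1])
    own <- m[corpus$doc %in% works1[1:2], , drop = FALSE]
    rest <- m[corpus$doc %in% works1[3:4], , drop = FALSE]
    other <- m[!a1, , drop = FALSE][seq_len(nrow(rest)), , drop = FALSE]
    same <- degradation_curve(own, rest, config, label = "same",
                              seed = ss[[2]])
    diff <- degradation_curve(own, other, config, label = "different",
                              seed = ss[[3]])
    c(same = same$accuracies[1] - same$accuracies[config$f],
      different = diff$accuracies[1] - diff$accuracies[config$f])
  }, numeric(2)))
  list(separation_rate = mean(drops[, "same"] > drops[, "different"]),
       drops = drops, n_runs = n_runs)
}
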