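# Insertion analyses: score a questioned or known-bogus work inside a
# candidate author's profile map.

#' Insert a candidate work into an author's map and score it
#'
#' Appends the candidate's feature row to the base author's feature table,
#' runs the full profile-map analysis on the union (so the candidate takes
#' part in center and covariance estimation, exactly as a provisionally
#' attributed work would), and reports the candidate's rank by grand score.
#' Rank 1 means the candidate has the lowest grand score of the whole map,
#' i.e. is the single worst fit; ties are broken against the insertion so
#' detection is never inflated. A base-only reference analysis (same seed)
#' is always computed alongside.
#'
#' @param base_features Feature table of the candidate author's verified
#'   works (at least 3 rows).
#' @param candidate One-row feature table for the questioned work, with the
#'   same variables.
#' @param scheme,B,seed,ridge Passed to [mpm_analyze()].
#' @return An object of class `mpm_insertion`: list with `run` (the
#'   `mpm_map` over base + candidate), `base` (base-only `mpm_map`),
#'   `inserted_doc_id`, `inserted_grand`, `inserted_rank`, `n_works`.
#' @export
insert_and_score <- function(base_features, candidate,
                             scheme = default_cluster_scheme(),
                             B = 1000, seed = NULL, ridge = 0) {
  if (nrow(base_features) < 3) {
    stop("base corpus must contain at least 3 works", call. = FALSE)
  }
  if (nrow(candidate) != 1) {
    stop("`candidate` must be a single-row feature table", call. = FALSE)
  }
  if (candidate$doc_id %in% base_features$doc_id) {
    stop("candidate doc_id '", candidate$doc_id,
         "' collides with a base work", call. = FALSE)
  }
  common <- intersect(names(base_features), names(candidate))
  joint <- rbind(base_features[, common, drop = FALSE],
                 candidate[, common, drop = FALSE])
  run <- mpm_analyze(joint, scheme = scheme, B = B, seed = seed,
                     ridge = ridge)
  base <- mpm_analyze(base_features[, common, drop = FALSE], scheme = scheme,
                      B = B, seed = seed, ridge = ridge)
  g <- run$profiles$grand_score
  ins <- run$profiles$doc_id == candidate$doc_id
  # ties rank the inserted work after the tied base works
  rank_ins <- sum(g[!ins] <= g[ins]) + 1L
  structure(
    list(run = run, base = base,
         inserted_doc_id = candidate$doc_id,
         inserted_grand = g[ins],
         inserted_rank = rank_ins,
         n_works = length(g)),
    class = "mpm_insertion"
  )
}

#' @export
print.mpm_insertion <- function(x, ...) {
  cat(sprintf(
    "<mpm_insertion> '%s' into a map of %d works\n  grand score %.2f, rank %d of %d by ascending grand score\n",
    x$inserted_doc_id, x$n_works - 1L, x$inserted_grand, x$inserted_rank,
    x$n_works))
  invisible(x)
}

#' Average base-work scores across insertion runs
#'
#' Each insertion run rebuilds the map, so the base works' own grand scores
#' shift slightly from run to run. This averages every base work's grand
#' score across the runs and correlates the averages with the base-only
#' (no-insertion) analysis, as a stability check of the map under
#' insertions.
#'
#' @param runs List of `mpm_insertion` objects over the same base corpus
#'   (at least 2).
#' @return List with `averages` (data frame `doc_id`, `mean_grand`) and
#'   `base_correlation` (Pearson r with the base-only grand scores).
#' @export
average_runs <- function(runs) {
  stopifnot(length(runs) >= 2,
            all(vapply(runs, inherits, logical(1), "mpm_insertion")))
  base_ids <- lapply(runs, function(r) sort(r$base$profiles$doc_id))
  if (!all(vapply(base_ids[-1], identical, logical(1), base_ids[[1]]))) {
    stop("insertion runs were made over different base corpora",
         call. = FALSE)
  }
  ids <- runs[[1]]$base$profiles$doc_id
  per_run <- vapply(runs, function(r) {
    p <- r$run$profiles
    p$grand_score[match(ids, p$doc_id)]
  }, numeric(length(ids)))
  means <- rowMeans(per_run)
  base_grand <- runs[[1]]$base$profiles$grand_score
  list(
    averages = data.frame(doc_id = ids, mean_grand = means,
                          stringsAsFactors = FALSE),
    base_correlation = stats::cor(means, base_grand)
  )
}
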