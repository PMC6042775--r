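# Internal numerical and RNG helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state so package functions never disturb the
#' global random stream. With `seed = NULL` the code runs on the current
#' stream unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` sub-seeds (for independent seeded stages) from a parent seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}

#' Moore-Penrose pseudo-inverse of a symmetric matrix
#'
#' Eigenvalues below `tol` times the largest eigenvalue are treated as zero,
#' guarding Mahalanobis distances when the number of documents is close to
#' (or below) the cluster dimensionality. A zero matrix returns a zero
#' matrix.
#' @noRd
pinv_sym <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  thr <- tol * max(abs(e$values), 0)
  keep <- e$values > thr & e$values > 0
  if (!any(keep)) {
    return(matrix(0, nrow(S), ncol(S), dimnames = dimnames(S)))
  }
  V <- e$vectors[, keep, drop = FALSE]
  out <- V %*% (t(V) / e$values[keep])
  dimnames(out) <- dimnames(S)
  out
}

# Columns of a feature table that are not feature variables.
RESERVED_COLUMNS <- c("doc_id", "author", "word_count", "doc", "segment")

feature_columns <- function(features) {
  setdiff(names(features), RESERVED_COLUMNS)
}

feature_matrix <- function(features) {
  vars <- feature_columns(features)
  m <- as.matrix(features[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$doc_id
  m
}
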