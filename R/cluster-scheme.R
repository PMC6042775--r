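# Grouping of feature variables into clusters of psychological processes.

# The four proprietary summary variables: computed by the reference scoring
# software from undisclosed formulas, so they may legitimately be absent
# from feature tables built with open dictionaries.
SUMMARY_VARIABLES <- c("Analytic", "Clout", "Authentic", "Tone")

#' Cluster schemes
#'
#' A cluster scheme groups feature variables into named clusters of
#' psychological processes; distances are computed per cluster over its
#' member variables jointly. `default_cluster_scheme()` returns the standard
#' 13-cluster grouping of the LIWC2015 variables (Style, Complexity,
#' Function Words, Emotional, Social, Cognitive, Perceptual, Biological,
#' Motivational, Temporal, Relational, Personal, Utterances). A variable may
#' belong to more than one cluster (Analytic sits in both Style and
#' Complexity).
#'
#' @param clusters Named list of character vectors (cluster name ->
#'   member variable names), each with at least two members.
#' @return An object of class `mpm_scheme` (a named list of character
#'   vectors).
#' @export
cluster_scheme <- function(clusters) {
  stopifnot(is.list(clusters), length(clusters) >= 1)
  if (is.null(names(clusters)) || any(!nzchar(names(clusters)))) {
    stop("every cluster must be named", call. = FALSE)
  }
  sizes <- lengths(clusters)
  if (any(sizes < 2)) {
    stop("cluster(s) with fewer than 2 member variables: ",
         paste(names(clusters)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  structure(lapply(clusters, as.character), class = "mpm_scheme")
}

#' @rdname cluster_scheme
#' @export
default_cluster_scheme <- function() {
  cluster_scheme(list(
    Style         = c("Analytic", "Clout", "Authentic", "Tone"),
    Complexity    = c("Analytic", "Sixltr"),
    FunctionWords = c("i", "we", "you", "shehe", "they", "ipron", "article",
                      "prep", "auxverb", "adverb", "conj", "negate",
                      "interrog"),
    Emotional     = c("affect", "posemo", "negemo", "anx", "anger", "sad"),
    Social        = c("social", "family", "friend", "female", "male"),
    Cognitive     = c("cogproc", "insight", "cause", "discrep", "tentat",
                      "certain", "differ"),
    Perceptual    = c("percept", "see", "hear", "feel"),
    Biological    = c("bio", "body", "health", "sexual", "ingest"),
    Motivational  = c("drives", "affiliation", "achieve", "power", "reward",
                      "risk"),
    Temporal      = c("focuspast", "focuspresent", "focusfuture"),
    Relational    = c("relative", "motion", "space", "time"),
    Personal      = c("work", "leisure", "home", "money", "relig", "death"),
    Utterances    = c("informal", "swear", "assent", "nonflu")
  ))
}

#' @export
print.mpm_scheme <- function(x, ...) {
  cat("<mpm_scheme>", length(x), "clusters\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 14), paste(x[[nm]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a feature table into per-cluster matrices
#'
#' Returns one documents-by-variables matrix per cluster, all sharing the
#' same document order (row names = `doc_id`). Summary variables missing
#' from the table (their formulas are proprietary) are dropped from the
#' scheme with a warning; any other missing variable is an error, as is a
#' cluster left with fewer than two members after drops.
#'
#' @param features Feature table (see [score_corpus()] / [read_features()]).
#' @param scheme An `mpm_scheme`; defaults to [default_cluster_scheme()].
#' @return Named list of numeric matrices. The (possibly reduced) scheme is
#'   attached as attribute `"scheme"`.
#' @export
build_cluster_matrices <- function(features, scheme = default_cluster_scheme()) {
  stopifnot(inherits(scheme, "mpm_scheme"))
  have <- feature_columns(features)
  wanted <- unique(unlist(scheme))
  missing_vars <- setdiff(wanted, have)
  droppable <- intersect(missing_vars, SUMMARY_VARIABLES)
  hard_missing <- setdiff(missing_vars, SUMMARY_VARIABLES)
  if (length(hard_missing) > 0) {
    stop("feature table is missing cluster variable(s): ",
         paste(hard_missing, collapse = ", "), call. = FALSE)
  }
  if (length(droppable) > 0) {
    warning("summary variable(s) absent from feature table, dropped from ",
            "scheme: ", paste(droppable, collapse = ", "), call. = FALSE)
    reduced <- lapply(unclass(scheme), setdiff, y = droppable)
    short <- names(reduced)[lengths(reduced) < 2]
    if (length(short) > 0) {
      stop("cluster(s) left with fewer than 2 variables after dropping ",
           "missing summary variables: ", paste(short, collapse = ", "),
           call. = FALSE)
    }
    scheme <- cluster_scheme(reduced)
  }
  m <- feature_matrix(features)
  out <- lapply(scheme, function(vars) m[, vars, drop = FALSE])
  attr(out, "scheme") <- scheme
  out
}
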