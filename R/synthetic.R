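# Seeded generators for synthetic authors, feature tables, segmented
# corpora and toy text corpora.

#' Define a synthetic author profile
#'
#' An author is modelled as a multivariate normal distribution over the
#' feature variables: a mean vector (the author's psychological center, in
#' feature-score units on the 0-100 scale) and a covariance describing
#' within-author variation from document to document.
#'
#' @param author_id Author name.
#' @param mean Named numeric vector of variable means, each in `[0, 100]`.
#' @param cov Covariance matrix over the same variables, or a single
#'   within-author standard deviation used for an isotropic (diagonal)
#'   covariance.
#' @param doc_length Token length used when rendering documents as text.
#' @return An object of class `author_profile`.
#' @export
author_profile <- function(author_id, mean, cov = 2.5, doc_length = 1000) {
  stopifnot(is.numeric(mean), !is.null(names(mean)))
  if (any(mean < 0 | mean > 100)) {
    stop("profile means must lie in [0, 100]", call. = FALSE)
  }
  p <- length(mean)
  if (is.matrix(cov)) {
    stopifnot(nrow(cov) == p, ncol(cov) == p)
  } else {
    stopifnot(length(cov) == 1, cov >= 0)
    cov <- diag(rep(cov^2, p))
  }
  dimnames(cov) <- list(names(mean), names(mean))
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance is not positive semi-definite", call. = FALSE)
  }
  structure(list(author_id = author_id, mean = mean, cov = cov,
                 doc_length = as.integer(doc_length)),
            class = "author_profile")
}

# PSD-tolerant multivariate normal sampler (eigen square root).
rmvnorm_psd <- function(n, mean, cov) {
  p <- length(mean)
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% t(L), 2, mean, "+")
}

#' Generate a feature table from author profiles
#'
#' Draws each document's feature vector from its author's multivariate
#' normal distribution and clips the result to the `[0, 100]` score range.
#' Deterministic given the seed; generator parameters are attached as
#' attribute `"params"`.
#'
#' @param profiles List of [author_profile()] objects (sharing variables).
#' @param docs_per_author Documents drawn per author.
#' @param seed Optional seed.
#' @return Feature table data frame (`doc_id`, `author`, `word_count`,
#'   variables).
#' @export
gen_author_feature_table <- function(profiles, docs_per_author, seed = NULL) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "author_profile")))
  vars <- names(profiles[[1]]$mean)
  rows <- with_seed(seed, {
    lapply(profiles, function(pr) {
      stopifnot(identical(names(pr$mean), vars))
      X <- rmvnorm_psd(docs_per_author, pr$mean, pr$cov)
      X <- pmin(pmax(X, 0), 100)
      colnames(X) <- vars
      out <- data.frame(
        doc_id = sprintf("%s_doc%02d", pr$author_id,
                         seq_len(docs_per_author)),
        author = pr$author_id,
        word_count = pr$doc_length,
        stringsAsFactors = FALSE
      )
      cbind(out, as.data.frame(X))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- list(docs_per_author = docs_per_author, seed = seed,
                              authors = vapply(profiles, `[[`, character(1),
                                               "author_id"))
  out
}

#' Generate a set of benchmark author profiles
#'
#' The default benchmark emulates a handful of contemporaneous authors:
#' variable means are drawn per author around a common base level with a
#' between-author spread twice the within-author document-to-document
#' spread, so authors are distinct but overlapping -- the regime in which
#' both the profile map and unmasking are informative.
#'
#' @param n_authors Number of authors (default 6).
#' @param variables Character vector of variable names; defaults to the
#'   members of [default_cluster_scheme()] (minus the proprietary summary
#'   variables, plus `Sixltr`).
#' @param base_mean Common base level of the variable means (default 50).
#' @param within_sd Within-author document SD (default 2.5).
#' @param between_sd Between-author SD of the means (default
#'   `2 * within_sd`).
#' @param doc_length Token length recorded per document.
#' @param seed Optional seed.
#' @return List of [author_profile()] objects.
#' @export
synthetic_author_profiles <- function(n_authors = 6,
                                      variables = default_variables(),
                                      base_mean = 50, within_sd = 2.5,
                                      between_sd = 2 * within_sd,
                                      doc_length = 1000, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n_authors), function(i) {
      mu <- stats::rnorm(length(variables), base_mean, between_sd)
      mu <- pmin(pmax(mu, 0), 100)
      names(mu) <- variables
      author_profile(sprintf("author%02d", i), mu, cov = within_sd,
                     doc_length = doc_length)
    })
  })
}

#' Variables of the default cluster scheme that open dictionaries can score
#'
#' All member variables of [default_cluster_scheme()] except the four
#' proprietary summary variables, with `Sixltr` retained (it is computed
#' directly from token lengths). Used as the default feature space of the
#' synthetic generators.
#'
#' @return Character vector of variable names.
#' @export
default_variables <- function() {
  vars <- unique(unlist(default_cluster_scheme()))
  setdiff(vars, SUMMARY_VARIABLES)
}

#' Generate a segmented corpus for unmasking experiments
#'
#' Emulates the structure unmasking exploits: every author has a stable
#' profile, every work adds "superficial" offsets on a few randomly chosen
#' variables (themes, settings), and segments scatter around the work's
#' level. Same-author comparisons are then separable mostly through the few
#' superficial variables, whose removal collapses accuracy, while
#' different-author comparisons stay separable on the profile-wide
#' differences.
#'
#' @param n_authors,works_per_author,segments_per_work Corpus shape.
#' @param variables Feature variable names.
#' @param within_sd Segment-level noise SD (default 2.5).
#' @param between_sd Between-author SD of profile means (default
#'   `2 * within_sd`).
#' @param n_superficial Number of variables carrying per-work offsets
#'   (default 4).
#' @param superficial_sd SD of the per-work offsets (default
#'   `3 * within_sd`).
#' @param seed Optional seed.
#' @return Segment-level feature table with columns `doc_id`, `author`,
#'   `doc`, `segment`, `word_count` and the variables.
#' @export
gen_segment_corpus <- function(n_authors = 6, works_per_author = 15,
                               segments_per_work = 8,
                               variables = default_variables(),
                               within_sd = 2.5,
                               between_sd = 2 * within_sd,
                               n_superficial = 4,
                               superficial_sd = 3 * within_sd,
                               seed = NULL) {
  p <- length(variables)
  stopifnot(n_superficial >= 1, n_superficial <= p)
  with_seed(seed, {
    rows <- list()
    for (a in seq_len(n_authors)) {
      author <- sprintf("author%02d", a)
      mu <- pmin(pmax(stats::rnorm(p, 50, between_sd), 0), 100)
      for (w in seq_len(works_per_author)) {
        work <- sprintf("%s_work%02d", author, w)
        offset <- numeric(p)
        sup <- sample.int(p, n_superficial)
        offset[sup] <- stats::rnorm(n_superficial, 0, superficial_sd)
        S <- matrix(stats::rnorm(segments_per_work * p, 0, within_sd),
                    segments_per_work, p)
        S <- sweep(S, 2, mu + offset, "+")
        S <- pmin(pmax(S, 0), 100)
        colnames(S) <- variables
        out <- data.frame(
          doc_id = sprintf("%s_s%02d", work, seq_len(segments_per_work)),
          author = author, doc = work,
          segment = seq_len(segments_per_work),
          word_count = 250L, stringsAsFactors = FALSE
        )
        rows[[length(rows) + 1L]] <- cbind(out, as.data.frame(S))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Render a toy text corpus with known category rates
#'
#' Writes `n_docs` plain-text documents whose expected dictionary category
#' percentages match `targets`: each token is, independently, a word of
#' category `c` with probability `targets[c] / 100`, otherwise a filler
#' token outside the dictionary. Scoring the output with [score_text()]
#' therefore recovers the targets up to binomial sampling error. Each
#' category's emitting word is a literal dictionary entry belonging to that
#' category alone, so targets for disjoint categories must sum to at most
#' 100. The generator parameters are written next to the corpus in a
#' `GENERATOR` metadata file, and output is byte-identical for a given
#' seed.
#'
#' @param targets Named vector of target percentages (names = category
#'   names in `lexicon`).
#' @param lexicon An `mpm_lexicon`.
#' @param n_docs Number of documents.
#' @param dir Output directory; documents go to `dir/<author_id>/`.
#' @param author_id Author directory name (default `"toy_author"`).
#' @param doc_length Tokens per document (default 1000).
#' @param seed Optional seed.
#' @return The author directory path, invisibly.
#' @export
gen_toy_corpus <- function(targets, lexicon, n_docs, dir,
                           author_id = "toy_author", doc_length = 1000,
                           seed = NULL) {
  stopifnot(inherits(lexicon, "mpm_lexicon"), !is.null(names(targets)),
            all(targets >= 0))
  if (sum(targets) > 100) {
    stop("target percentages sum to more than 100", call. = FALSE)
  }
  unknown <- setdiff(names(targets), lexicon$categories$name)
  if (length(unknown) > 0) {
    stop("target category not in lexicon: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # one literal, single-category word per target category
  words <- vapply(names(targets), function(nm) {
    id <- lexicon$categories$id[lexicon$categories$name == nm]
    ent <- lexicon$entries
    ok <- !ent$is_prefix &
      vapply(ent$category_ids, function(ids) identical(ids, id), logical(1))
    # the word must not also match any prefix stem
    stems <- ent$pattern[ent$is_prefix]
    ok <- ok & !vapply(ent$pattern, function(p) {
      length(stems) > 0 && any(startsWith(p, stems))
    }, logical(1))
    if (!any(ok)) {
      stop("no single-category literal word available for category '",
           nm, "'", call. = FALSE)
    }
    ent$pattern[ok][1]
  }, character(1))
  filler <- "xq"
  while (any(startsWith(filler, lexicon$entries$pattern[lexicon$entries$is_prefix])) ||
         filler %in% lexicon$entries$pattern) {
    filler <- paste0(filler, "x")
  }
  adir <- file.path(dir, author_id)
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  probs <- c(targets / 100, filler = 1 - sum(targets) / 100)
  vocab <- c(unname(words), filler)
  with_seed(seed, {
    for (d in seq_len(n_docs)) {
      toks <- sample(vocab, doc_length, replace = TRUE, prob = probs)
      path <- file.path(adir, sprintf("doc%03d.txt", d))
      writeLines(paste(toks, collapse = " "), path, useBytes = TRUE)
    }
  })
  meta <- data.frame(
    author_id = author_id, n_docs = n_docs, doc_length = doc_length,
    seed = if (is.null(seed)) NA else seed,
    targets = paste(sprintf("%s=%g", names(targets), targets),
                    collapse = "; ")
  )
  write.dcf(meta, file.path(dir, "GENERATOR"))
  invisible(adir)
}
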