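# Unmasking baseline: degradation of linear-SVM accuracy under iterative
# elimination of the most discriminative features, and a meta-learner over
# the degradation curves.

#' Configuration for the unmasking procedure
#'
#' @param f Number of feature-elimination iterations (default 10).
#' @param k Features removed per sign per iteration: the `k` largest
#'   positive and `k` most negative SVM weights, `2k` in total (default 2).
#' @param cv_folds Stratified cross-validation folds used to estimate the
#'   per-iteration accuracy (default 5).
#' @param n_iterations Randomized repetitions over which attribution
#'   probabilities are averaged (default 20).
#' @param cost Linear-SVM regularization constant C (default 1).
#' @param seed Optional seed.
#' @return An object of class `unmasking_config`.
#' @export
unmasking_config <- function(f = 10, k = 2, cv_folds = 5,
                             n_iterations = 20, cost = 1, seed = NULL) {
  stopifnot(f >= 2, k >= 1, cv_folds >= 2, n_iterations >= 1, cost > 0)
  structure(list(f = as.integer(f), k = as.integer(k),
                 cv_folds = as.integer(cv_folds),
                 n_iterations = as.integer(n_iterations),
                 cost = cost, seed = seed),
            class = "unmasking_config")
}

# Stratified CV accuracy of a linear SVM separating the two classes.
svm_cv_accuracy <- function(X, y, cv_folds, cost) {
  n <- length(y)
  folds <- integer(n)
  for (cls in levels(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  correct <- 0L
  for (fold in seq_len(cv_folds)) {
    test <- folds == fold
    if (!any(test) || length(unique(y[!test])) < 2) next
    fit <- e1071::svm(X[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, X[test, , drop = FALSE])
    correct <- correct + sum(pred == y[test])
  }
  correct / n
}

# Signed weight vector of a linear SVM fit on all current data.
svm_weights <- function(X, y, cost) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(X)
  w
}

#' Prediction degradation curve between two segment sets
#'
#' Runs `f` iterations: estimate the stratified cross-validated accuracy of
#' a linear SVM separating `set_a` from `set_b` on the current features,
#' then refit on all current data and remove the `k` features with the
#' largest positive and the `k` with the most negative weights. Same-author
#' pairs rely on a few superficial discriminators, so their accuracy
#' degrades quickly; different-author pairs stay separable. Features are
#' standardized over the pooled sets before the iterations start. Derived
#' curve features are least-squares linear and quadratic trend
#' coefficients of accuracy against iteration index and the lag-1 / lag-2
#' accuracy drops.
#'
#' @param set_a,set_b Segment feature matrices (segments x variables) with
#'   identical column sets; each needs at least `cv_folds` rows.
#' @param config An [unmasking_config()].
#' @param label Optional curve label: `"same"`, `"different"` or
#'   `"unknown"`.
#' @param seed Optional seed for the fold assignments.
#' @return An object of class `degradation_curve`: list with `accuracies`
#'   (length `f`), `linear_beta`, `quad_betas` (length 2), `deltas1`,
#'   `deltas2`, `label`, `f`, `k`.
#' @export
degradation_curve <- function(set_a, set_b, config = unmasking_config(),
                              label = "unknown", seed = config$seed) {
  A <- as.matrix(set_a)
  Bm <- as.matrix(set_b)
  if (!identical(colnames(A), colnames(Bm))) {
    common <- intersect(colnames(A), colnames(Bm))
    if (length(common) < ncol(A) || length(common) < ncol(Bm)) {
      stop("segment sets do not share a common feature space", call. = FALSE)
    }
    Bm <- Bm[, colnames(A), drop = FALSE]
  }
  f <- config$f
  k <- config$k
  if (2 * k * f > ncol(A)) {
    stop("2*k*f = ", 2 * k * f, " exceeds the ", ncol(A),
         " available features; lower f or k", call. = FALSE)
  }
  if (nrow(A) < config$cv_folds || nrow(Bm) < config$cv_folds) {
    stop("each segment set needs at least cv_folds = ", config$cv_folds,
         " rows", call. = FALSE)
  }
  X <- rbind(A, Bm)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  y <- factor(rep(c("a", "b"), c(nrow(A), nrow(Bm))))
  acc <- numeric(f)
  with_seed(seed, {
    for (i in seq_len(f)) {
      acc[i] <- svm_cv_accuracy(X, y, config$cv_folds, config$cost)
      w <- svm_weights(X, y, config$cost)
      ord <- order(w)
      drop_idx <- c(utils::head(ord, k), utils::tail(ord, k))
      X <- X[, -drop_idx, drop = FALSE]
    }
  })
  iter <- seq_len(f)
  lin <- stats::lm.fit(cbind(1, iter), acc)$coefficients[2]
  quad <- stats::lm.fit(cbind(1, iter, iter^2), acc)$coefficients[2:3]
  structure(
    list(accuracies = acc,
         linear_beta = unname(lin),
         quad_betas = unname(quad),
         deltas1 = acc[seq_len(f - 1)] - acc[-1],
         deltas2 = acc[seq_len(f - 2)] - acc[-(1:2)],
         label = label, f = f, k = k),
    class = "degradation_curve"
  )
}

#' @export
print.degradation_curve <- function(x, ...) {
  cat("<degradation_curve>", x$label, "\n  accuracies:",
      paste(sprintf("%.2f", x$accuracies), collapse = " "), "\n")
  invisible(x)
}

#' Flatten a degradation curve into the meta-learner feature vector
#'
#' Concatenates the `f` accuracies, the linear and quadratic trend
#' coefficients, and the lag-1 and lag-2 accuracy drops (`3f` values for an
#' `f`-iteration curve).
#'
#' @param curve A `degradation_curve`.
#' @return Named numeric vector.
#' @export
curve_features <- function(curve) {
  stopifnot(inherits(curve, "degradation_curve"))
  v <- c(curve$accuracies, curve$linear_beta, curve$quad_betas,
         curve$deltas1, curve$deltas2)
  names(v) <- c(paste0("acc", seq_len(curve$f)), "beta_lin", "beta_q1",
                "beta_q2", paste0("d1_", seq_len(curve$f - 1)),
                paste0("d2_", seq_len(curve$f - 2)))
  v
}

#' Build labeled training curves from a segmented corpus
#'
#' For every work of every author with at least two works, two curves are
#' built leave-one-work-out: the work's segments against the rest of the
#' author's segments (label `"same"`), and the work's segments against an
#' equally sized amalgam of segments drawn evenly from the other authors
#' (label `"different"`).
#'
#' @param features Segment-level feature table with columns `doc_id`,
#'   `author`, `doc` (parent work) and the feature variables.
#' @param config An [unmasking_config()].
#' @param seed Optional seed.
#' @return List of `degradation_curve` objects with attribute `"works"`
#'   (data frame of work, author, label per curve).
#' @export
build_training_curves <- function(features, config = unmasking_config(),
                                  seed = config$seed) {
  stopifnot(all(c("author", "doc") %in% names(features)))
  m <- feature_matrix(features)
  author <- features$author
  work <- features$doc
  works <- unique(data.frame(author = author, work = work,
                             stringsAsFactors = FALSE))
  counts <- table(works$author)
  eligible <- names(counts)[counts >= 2]
  curves <- list()
  meta <- list()
  seeds <- derive_seeds(seed, 2L * nrow(works))
  si <- 0L
  for (i in seq_len(nrow(works))) {
    a <- works$author[i]
    w <- works$work[i]
    if (!(a %in% eligible)) next
    own <- m[work == w, , drop = FALSE]
    rest <- m[author == a & work != w, , drop = FALSE]
    si <- si + 1L
    curves[[length(curves) + 1L]] <-
      degradation_curve(own, rest, config, label = "same",
                        seed = seeds[[si]])
    meta[[length(meta) + 1L]] <- data.frame(work = w, author = a,
                                            label = "same")
    others <- m[author != a, , drop = FALSE]
    si <- si + 1L
    curves[[length(curves) + 1L]] <- with_seed(seeds[[si]], {
      take <- sample.int(nrow(others), min(nrow(rest), nrow(others)))
      degradation_curve(own, others[take, , drop = FALSE], config,
                        label = "different", seed = NULL)
    })
    meta[[length(meta) + 1L]] <- data.frame(work = w, author = a,
                                            label = "different")
  }
  attr(curves, "works") <- do.call(rbind, meta)
  curves
}

#' Train the meta-learner over labeled degradation curves
#'
#' A linear SVM with Platt-scaled probability outputs, fit on the flattened
#' curve features (see [curve_features()]). The meta-learner is what turns
#' a degradation curve into a same-author / different-author verdict.
#'
#' @param curves List of labeled `degradation_curve` objects (both labels
#'   present).
#' @param config An [unmasking_config()].
#' @return An object of class `meta_learner`.
#' @export
train_meta_learner <- function(curves, config = unmasking_config()) {
  labels <- vapply(curves, `[[`, character(1), "label")
  if (length(unique(labels)) < 2) {
    stop("training curves carry a single label; need both 'same' and ",
         "'different'", call. = FALSE)
  }
  X <- t(vapply(curves, curve_features,
                numeric(3L * config$f)))
  y <- factor(labels, levels = c("different", "same"))
  fit <- e1071::svm(X, y, kernel = "linear", cost = config$cost,
                    probability = TRUE, scale = TRUE)
  structure(list(model = fit, f = config$f, config = config),
            class = "meta_learner")
}

#' Classify degradation curves with a trained meta-learner
#'
#' @param meta A `meta_learner`.
#' @param curves List of `degradation_curve` objects.
#' @return Data frame with columns `label` (predicted) and `p_same`.
#' @export
predict_curves <- function(meta, curves) {
  stopifnot(inherits(meta, "meta_learner"))
  X <- t(vapply(curves, curve_features, numeric(3L * meta$f)))
  pred <- stats::predict(meta$model, X, probability = TRUE)
  p <- attr(pred, "probabilities")[, "same"]
  data.frame(label = as.character(pred), p_same = unname(p),
             stringsAsFactors = FALSE)
}

#' Attribute a questioned work to a candidate author
#'
#' Builds the questioned-vs-candidate degradation curve under
#' `n_iterations` randomized fold assignments, classifies each curve with
#' the meta-learner, and averages the calibrated same-author
#' probabilities. The verdict is `"Match"` when the average probability of
#' same authorship is at least 0.5.
#'
#' @param questioned Segment feature matrix of the questioned work.
#' @param candidate_segments Segment feature matrix of the candidate
#'   author's known works.
#' @param meta A trained `meta_learner`.
#' @param config An [unmasking_config()]; `n_iterations` controls the
#'   averaging.
#' @param seed Optional seed.
#' @return An object of class `attribution_result`: list with `verdict`
#'   (`"Match"` / `"Different"`), `probability` (calibrated confidence in
#'   the verdict), `p_same`, `n_iterations`.
#' @export
attribute_work <- function(questioned, candidate_segments, meta,
                           config = unmasking_config(),
                           seed = config$seed) {
  if (nrow(questioned) < config$cv_folds) {
    stop("questioned work yields fewer than cv_folds = ", config$cv_folds,
         " segments", call. = FALSE)
  }
  seeds <- derive_seeds(seed, config$n_iterations)
  p_same <- vapply(seeds, function(s) {
    curve <- degradation_curve(questioned, candidate_segments, config,
                               seed = s)
    predict_curves(meta, list(curve))$p_same
  }, numeric(1))
  p <- mean(p_same)
  verdict <- if (p >= 0.5) "Match" else "Different"
  structure(
    list(verdict = verdict,
         probability = if (p >= 0.5) p else 1 - p,
         p_same = p, n_iterations = config$n_iterations),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s (%.2f%%), averaged over %d runs\n",
              x$verdict, 100 * x$probability, x$n_iterations))
  invisible(x)
}

#' Accuracy, class-balanced accuracy and Cohen's kappa
#'
#' Kappa uses the marginal-product chance agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param predictions,truths Equal-length label vectors.
#' @return List with `accuracy`, `balanced_accuracy`, `kappa`.
#' @examples
#' evaluate_predictions(c("a", "a", "b"), c("a", "b", "b"))
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  }
  lev <- union(truths, predictions)
  pred <- factor(predictions, levels = lev)
  tru <- factor(truths, levels = lev)
  tab <- table(tru, pred)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  recalls <- diag(tab) / rowSums(tab)
  list(
    accuracy = po,
    balanced_accuracy = mean(recalls[rowSums(tab) > 0]),
    kappa = if (pe >= 1) 1 else (po - pe) / (1 - pe)
  )
}

#' Synthetic unmasking benchmark
#'
#' Generates a segmented multi-author corpus with
#' [gen_segment_corpus()], holds out part of each author's works, trains
#' the meta-learner on curves from the training works and evaluates it on
#' curves from the held-out works, repeating the whole cycle under
#' `n_reps` seeds.
#'
#' @param n_authors,works_per_author,segments_per_work Corpus shape.
#' @param holdout_per_author Works per author reserved for evaluation.
#' @param config An [unmasking_config()].
#' @param n_reps Randomized repetitions averaged over (default 3).
#' @param seed Optional seed.
#' @param ... Passed to [gen_segment_corpus()].
#' @return List with `accuracy`, `balanced_accuracy`, `kappa` (averages
#'   over repetitions) and `per_rep` (data frame of the per-repetition
#'   values).
#' @export
unmasking_benchmark <- function(n_authors = 6, works_per_author = 15,
                                segments_per_work = 8,
                                holdout_per_author = 5,
                                config = unmasking_config(),
                                n_reps = 3, seed = NULL, ...) {
  stopifnot(holdout_per_author >= 1,
            works_per_author > holdout_per_author + 1)
  seeds <- derive_seeds(seed, n_reps)
  rep_res <- lapply(seeds, function(s) {
    ss <- derive_seeds(s, 4)
    corpus <- gen_segment_corpus(n_authors = n_authors,
                                 works_per_author = works_per_author,
                                 segments_per_work = segments_per_work,
                                 seed = ss[[1]], ...)
    works <- unique(corpus[, c("author", "doc")])
    hold <- with_seed(ss[[2]], {
      unlist(lapply(split(works$doc, works$author), function(w) {
        sample(w, holdout_per_author)
      }))
    })
    train_tab <- corpus[!(corpus$doc %in% hold), ]
    test_tab <- corpus[corpus$doc %in% hold, ]
    train_curves <- build_training_curves(train_tab, config,
                                          seed = ss[[3]])
    meta <- train_meta_learner(train_curves, config)
    # test curves: held-out work vs the candidate's training works (same)
    # and vs an amalgam of other authors' training segments (different)
    m_train <- feature_matrix(train_tab)
    m_test <- feature_matrix(test_tab)
    truth <- character(0)
    curves <- list()
    tseeds <- derive_seeds(ss[[4]], 2L * length(hold))
    ti <- 0L
    for (w in hold) {
      a <- works$author[works$doc == w][1]
      own <- m_test[test_tab$doc == w, , drop = FALSE]
      rest <- m_train[train_tab$author == a, , drop = FALSE]
      others <- m_train[train_tab$author != a, , drop = FALSE]
      ti <- ti + 1L
      curves[[length(curves) + 1L]] <-
        degradation_curve(own, rest, config, seed = tseeds[[ti]])
      truth <- c(truth, "same")
      ti <- ti + 1L
      curves[[length(curves) + 1L]] <- with_seed(tseeds[[ti]], {
        take <- sample.int(nrow(others), min(nrow(rest), nrow(others)))
        degradation_curve(own, others[take, , drop = FALSE], config,
                          seed = NULL)
      })
      truth <- c(truth, "different")
    }
    pred <- predict_curves(meta, curves)$label
    evaluate_predictions(pred, truth)
  })
  per_rep <- data.frame(
    accuracy = vapply(rep_res, `[[`, numeric(1), "accuracy"),
    balanced_accuracy = vapply(rep_res, `[[`, numeric(1),
                               "balanced_accuracy"),
    kappa = vapply(rep_res, `[[`, numeric(1), "kappa")
  )
  list(accuracy = mean(per_rep$accuracy),
       balanced_accuracy = mean(per_rep$balanced_accuracy),
       kappa = mean(per_rep$kappa),
       per_rep = per_rep)
}
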