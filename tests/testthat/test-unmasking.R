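# Smaller-than-default elimination settings keep these unit tests quick;
# the full benchmark regime runs in the acceptance suite.
quick_config <- function(...) {
  unmasking_config(f = 5, k = 2, cv_folds = 4, n_iterations = 3, ...)
}

test_that("unmasking_config validates its parameters", {
  expect_s3_class(unmasking_config(), "unmasking_config")
  expect_error(unmasking_config(f = 1), "f >= 2")
  expect_error(unmasking_config(k = 0), "k >= 1")
})

test_that("identical segment sets give chance-level degradation curves", {
  set.seed(101)
  X <- matrix(rnorm(20 * 30, 50, 3), 20, 30,
              dimnames = list(NULL, paste0("v", 1:30)))
  cur <- degradation_curve(X, X, quick_config(), seed = 102)
  expect_length(cur$accuracies, 5)
  expect_true(all(cur$accuracies >= 0 & cur$accuracies <= 1))
  expect_lt(mean(cur$accuracies), 0.7)
})

test_that("degradation_curve enforces the feature and segment budgets", {
  set.seed(103)
  X <- matrix(rnorm(10 * 15), 10, 15, dimnames = list(NULL, paste0("v", 1:15)))
  Y <- X + 1
  # 2*k*f = 20 exceeds 15 features
  expect_error(degradation_curve(X, Y, quick_config()), "exceeds")
  cfg <- unmasking_config(f = 3, k = 2, cv_folds = 4)
  expect_error(degradation_curve(X[1:2, ], Y, cfg), "cv_folds")
  cur <- degradation_curve(X, Y, cfg, seed = 104)
  expect_length(cur$accuracies, 3)
  expect_length(cur$deltas1, 2)
  expect_length(cur$deltas2, 1)
  v <- curve_features(cur)
  expect_length(v, 3 * cfg$f)
  expect_equal(unname(v[1:3]), cur$accuracies)
})

test_that("same-author curves degrade faster than different-author curves", {
  us <- unmasking_separation(n_runs = 10, config = quick_config(),
                             seed = 105)
  expect_gte(us$separation_rate, 0.8)
})

test_that("the meta-learner separates cleanly separable curve families", {
  set.seed(106)
  cfg <- quick_config()
  fake_curve <- function(label) {
    acc <- if (label == "same") seq(0.95, 0.5, length.out = 5) +
      rnorm(5, 0, 0.01) else rep(0.95, 5) + rnorm(5, 0, 0.01)
    iter <- 1:5
    structure(list(
      accuracies = acc,
      linear_beta = unname(lm.fit(cbind(1, iter), acc)$coefficients[2]),
      quad_betas = unname(lm.fit(cbind(1, iter, iter^2),
                                 acc)$coefficients[2:3]),
      deltas1 = acc[1:4] - acc[2:5], deltas2 = acc[1:3] - acc[3:5],
      label = label, f = 5L, k = 2L), class = "degradation_curve")
  }
  curves <- c(lapply(1:8, function(i) fake_curve("same")),
              lapply(1:8, function(i) fake_curve("different")))
  meta <- train_meta_learner(curves, cfg)
  pred <- predict_curves(meta, curves)
  expect_equal(pred$label, vapply(curves, `[[`, character(1), "label"))
  expect_error(train_meta_learner(curves[1:8], cfg), "single label")
})

test_that("attribution verdicts are sensible and order-invariant", {
  cfg <- quick_config()
  corpus <- gen_segment_corpus(n_authors = 3, works_per_author = 5,
                               segments_per_work = 8, seed = 107)
  hold <- c("author01_work05", "author02_work05")
  train_tab <- corpus[!(corpus$doc %in% hold), ]
  curves <- build_training_curves(train_tab, cfg, seed = 108)
  meta <- train_meta_learner(curves, cfg)
  m <- mpmap:::feature_matrix(corpus)
  own <- m[corpus$doc == "author01_work05", , drop = FALSE]
  cand <- m[corpus$author == "author01" & !(corpus$doc %in% hold), ,
            drop = FALSE]
  res_same <- attribute_work(own, cand, meta, cfg, seed = 109)
  expect_s3_class(res_same, "attribution_result")
  expect_equal(res_same$verdict, "Match")
  other <- m[corpus$doc == "author02_work05", , drop = FALSE]
  res_diff <- attribute_work(other, cand, meta, cfg, seed = 109)
  expect_equal(res_diff$verdict, "Different")
  expect_gte(res_diff$probability, 0.5)
  # permuting the questioned segments does not change the verdict
  res_perm <- attribute_work(own[sample(nrow(own)), , drop = FALSE],
                             cand, meta, cfg, seed = 109)
  expect_equal(res_perm$verdict, res_same$verdict)
})

test_that("evaluate_predictions computes accuracy, balance and kappa", {
  expect_equal(evaluate_predictions(c("a", "b"), c("a", "b")),
               list(accuracy = 1, balanced_accuracy = 1, kappa = 1))
  # all-one-class predictions on a balanced truth set: kappa 0
  ev <- evaluate_predictions(rep("a", 10), rep(c("a", "b"), 5))
  expect_equal(ev$kappa, 0)
  # hand-computed 2x2 table: TP=8, TN=8, FP=1, FN=1
  pred <- c(rep("pos", 8), "neg", rep("neg", 8), "pos")
  truth <- c(rep("pos", 9), rep("neg", 9))
  ev2 <- evaluate_predictions(pred, truth)
  expect_equal(ev2$kappa, 0.778, tolerance = 1e-3)
  expect_equal(ev2$accuracy, 16 / 18)
  expect_error(evaluate_predictions(character(0), character(0)),
               "non-empty")
})
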