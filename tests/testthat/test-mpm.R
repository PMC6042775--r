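test_that("fit_center_model handles constant data and matches the plain mean", {
  X <- matrix(rep(c(3, 7), each = 5), 5, 2,
              dimnames = list(NULL, c("a", "b")))
  m <- fit_center_model(X, B = 50, seed = 1)
  expect_equal(unname(m$center), c(3, 7))
  expect_true(all(m$cov == 0))
  expect_error(fit_center_model(X[1:2, ], B = 10), "at least 3")

  # law of large numbers: the bootstrap mean converges to the column mean
  set.seed(11)
  Y <- matrix(rnorm(60, 50, 2), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  m2 <- fit_center_model(Y, B = 50000, seed = 12)
  expect_lt(max(abs(m2$center - colMeans(Y))), 1e-2)
  # deterministic given the seed
  m3 <- fit_center_model(Y, B = 200, seed = 13)
  m4 <- fit_center_model(Y, B = 200, seed = 13)
  expect_identical(m3$center, m4$center)
})

test_that("chi-square mapping has the right endpoints and direction", {
  expect_equal(chisq_score(0, df = 4), 100)
  expect_equal(chisq_score(3.841, df = 1), 5.00, tolerance = 1e-2)
  d2 <- seq(0, 40, by = 0.5)
  s <- chisq_score(d2, df = 5)
  expect_true(all(diff(s) < 0))
  expect_lt(chisq_score(1e4, df = 13), 1e-8)
  expect_warning(s0 <- chisq_score(-0.1, df = 2), "clamped")
  expect_equal(s0, 100)
})

test_that("distance_scores reduces to squared Euclidean distance under identity covariance", {
  set.seed(21)
  X <- matrix(rnorm(30, 10, 2), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_center_model(X, B = 100, seed = 22)
  m$cov <- diag(3)
  dimnames(m$cov) <- list(m$variables, m$variables)
  prof <- distance_scores(list(cl = X), list(cl = m))
  expect_equal(unname(prof$d2[, "cl"]),
               unname(rowSums(sweep(X, 2, m$center)^2)))
  # a document exactly at the center scores 100
  X2 <- rbind(X, m$center)
  prof2 <- distance_scores(list(cl = X2), list(cl = m))
  expect_equal(unname(prof2$scores[11, "cl"]), 100)
  # dimension mismatch is an error
  expect_error(distance_scores(list(cl = X[, 1:2]), list(cl = m)),
               "variable mismatch")
})

test_that("Mahalanobis distances are invariant under invertible linear maps", {
  set.seed(31)
  X <- matrix(rnorm(200, 50, 3), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  A <- matrix(c(2, 0.5, 0, 0.3,
                0, 1.5, 0.2, 0,
                0.1, 0, 1.2, 0.4,
                0, 0.2, 0, 0.8), 4, 4)
  Y <- X %*% A
  colnames(Y) <- colnames(X)
  d2_x <- {
    m <- fit_center_model(X, B = 10, seed = 1)
    m$center <- colMeans(X)  # exact center so the comparison is algebraic
    distance_scores(list(cl = X), list(cl = m))$d2[, 1]
  }
  d2_y <- {
    m <- fit_center_model(Y, B = 10, seed = 1)
    m$center <- colMeans(Y)
    distance_scores(list(cl = Y), list(cl = m))$d2[, 1]
  }
  expect_equal(d2_x, d2_y, tolerance = 1e-6)
})

test_that("grand_score reproduces the published medians and basic properties", {
  tab <- load_table7_fixture()
  S <- as.matrix(tab[, cluster_names()])
  expect_equal(grand_score(S[tab$title == "The Lucky Chance", ]), 72.02)
  expect_equal(grand_score(S[tab$title == "The Revenge", ]), 49.78)
  expect_equal(grand_score(rep(37.5, 13)), 37.5)
  expect_equal(grand_score(c(a = 10, b = 20)), 15)  # even count: midpoint
  expect_error(grand_score(c(Style = 10, Emotional = NA)), "Emotional")
  # bounded by the extremes and invariant to cluster permutation
  set.seed(41)
  for (i in 1:10) {
    x <- runif(13, 0, 100)
    g <- grand_score(x)
    expect_gte(g, min(x)); expect_lte(g, max(x))
    expect_equal(grand_score(sample(x)), g)
  }
})

test_that("internal_consistency matches an independent covariance-trace formula", {
  set.seed(51)
  for (i in 1:5) {
    S <- matrix(rnorm(20 * 13, 50, 10), 20, 13)
    rep <- internal_consistency(S)
    C <- cov(S)
    k <- 13
    alpha_oracle <- k / (k - 1) * (1 - sum(diag(C)) / sum(C))
    expect_equal(rep$alpha, alpha_oracle, tolerance = 1e-12)
  }
  # two perfectly correlated items give alpha 1
  x <- rnorm(10)
  expect_equal(internal_consistency(cbind(x, x))$alpha, 1)
  expect_error(internal_consistency(matrix(5, 4, 3)), "zero")
})

test_that("project_map standardizes, orients and orders components", {
  # three collinear documents: the second coordinate collapses
  S <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(-1, -2, -3))
  co <- project_map(S)
  expect_lt(max(abs(co[, "pc2"])), 1e-8)
  # two components reconstruct at least as well as one
  set.seed(61)
  S <- matrix(rnorm(15 * 13, 50, 10), 15, 13)
  Z <- scale(S)
  pc <- prcomp(Z, center = FALSE)
  recon <- function(q) {
    R <- pc$x[, 1:q, drop = FALSE] %*% t(pc$rotation[, 1:q, drop = FALSE])
    sum((Z - R)^2)
  }
  expect_lte(recon(2), recon(1))
  # sign convention: the largest-magnitude loading is positive
  co2 <- project_map(S)
  expect_equal(dim(co2), c(15L, 2L))
  expect_error(project_map(matrix(5, 5, 3)), "non-zero variance")
})

test_that("decompose_profile flags the published discrepant clusters", {
  tab <- load_table7_fixture()
  row_of <- function(title) {
    s <- as.numeric(tab[tab$title == title, cluster_names()])
    names(s) <- cluster_names()
    s
  }
  expect_equal(decompose_profile(row_of("The Counterfeit Bridegroom")),
               c("Style", "Social", "Temporal", "Relational"))
  expect_equal(decompose_profile(row_of("The Debauchee")),
               c("Emotional", "Perceptual"))
  expect_equal(decompose_profile(row_of("The Woman Turned Bully")),
               c("Style", "Emotional", "Temporal", "Relational"))
  expect_equal(decompose_profile(row_of("The Lucky Chance")),
               c("Emotional", "Motivational"))
  s <- row_of("The Lucky Chance")
  expect_length(decompose_profile(s, threshold = 100), 13)
  expect_equal(decompose_profile(s + 100, threshold = 20), character(0))
})

test_that("mpm_analyze runs the full pipeline deterministically", {
  tab <- open_feature_table(n = 14)
  m1 <- mpm_analyze(tab, scheme = open_scheme(), B = 200, seed = 7)
  m2 <- mpm_analyze(tab, scheme = open_scheme(), B = 200, seed = 7)
  expect_equal(m1$profiles, m2$profiles)
  expect_true(all(m1$profiles$grand_score >= 0 &
                    m1$profiles$grand_score <= 100))
  scores <- as.matrix(m1$profiles[, names(open_scheme())])
  expect_equal(unname(apply(scores, 1, median)),
               m1$profiles$grand_score)
  expect_error(mpm_analyze(rbind(tab, tab)), "duplicate doc_id")
})
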