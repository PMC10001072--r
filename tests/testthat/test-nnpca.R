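test_that("single-gene set reduces to the centered gene with full variance", {
  set.seed(20)
  em <- lognorm_em(matrix(rexp(30), 30, 2))
  fit <- nnpca_fit(em, gene_set("S", "g1"), n_components = 1)
  expect_equal(unname(fit$loadings[, 1]), 1)
  expect_equal(fit$scores[, 1], em$values[, 1] - mean(em$values[, 1]))
  expect_equal(fit$variance_explained, 1)
})

test_that("two perfectly correlated equal-variance genes load equally", {
  x <- c(0, 1, 2, 5, 3, 8)
  em <- lognorm_em(cbind(x, x), gene_ids = c("g1", "g2"))
  fit <- nnpca_fit(em, gene_set("S", c("g1", "g2")), n_components = 1)
  expect_equal(unname(fit$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(fit$scores[, 1]), sqrt(2) * (x - mean(x)),
               tolerance = 1e-9)
})

test_that("component 1 matches the SVD oracle when the constraint is inactive", {
  set.seed(21)
  for (rep in 1:20) {
    X <- positive_factor_matrix()
    v1 <- leading_right_singular(X)
    while (any(v1 < 0)) { # redraw until the oracle premise holds
      X <- positive_factor_matrix()
      v1 <- leading_right_singular(X)
    }
    em <- lognorm_em(X)
    fit <- nnpca_fit(em, gene_set("S", em$gene_ids), n_components = 1)
    cosine <- sum(fit$loadings[, 1] * v1)
    expect_gte(cosine, 0.999)
    # objective ascent at every iteration of every fitted component
    for (tr in fit$objective_trace)
      expect_true(all(diff(tr) >= -1e-8 * max(tr)))
  }
})

test_that("loadings are non-negative unit vectors and scores are orthogonal", {
  set.seed(22)
  X <- matrix(rexp(60 * 12), 60, 12)
  em <- lognorm_em(X)
  fit <- nnpca_fit(em, gene_set("S", em$gene_ids), n_components = 4)
  expect_true(all(fit$loadings >= 0))
  expect_equal(unname(sqrt(colSums(fit$loadings^2))), rep(1, 4),
               tolerance = 1e-9)
  cors <- stats::cor(fit$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-6)
  expect_true(all(fit$variance_explained >= 0 & fit$variance_explained <= 1))
  # objective ascent holds here too, constraint active or not
  for (tr in fit$objective_trace)
    expect_true(all(diff(tr) >= -1e-8 * max(tr)))
})

test_that("anticorrelated gene pair collapses to a basis vector, matching grid search", {
  x <- c(1, 4, 2, 8, 5, 3)
  em <- lognorm_em(cbind(x, max(x) - x), gene_ids = c("g1", "g2"))
  fit <- suppressMessages(
    nnpca_fit(em, gene_set("S", c("g1", "g2")), n_components = 1))
  w <- fit$loadings[, 1]
  expect_true(all(sort(w) == c(0, 1)))
  # brute force over the non-negative unit quarter circle
  Xc <- sweep(em$values, 2, colMeans(em$values))
  theta <- seq(0, pi / 2, length.out = 20001)
  objective <- vapply(theta, function(t)
    var(Xc %*% c(cos(t), sin(t))), numeric(1))
  best <- c(cos(theta[which.max(objective)]), sin(theta[which.max(objective)]))
  expect_equal(unname(w), round(best), tolerance = 1e-9)
  expect_equal(var(drop(Xc %*% w)), max(objective), tolerance = 1e-6)
})

test_that("component ranking keeps top-variance candidates, reordered by subtype separation", {
  # constructed model: candidate selection by variance explained, then
  # re-ranking by the variance of per-subtype mean scores
  set.seed(23)
  labels <- rep(c("A", "B", "C"), each = 20)
  scores <- cbind(
    rnorm(60, 0, 3),                        # high variance, no separation
    rnorm(60, 0, 2.5),                      # high variance, no separation
    rep(c(-2, 0, 2), each = 20) + rnorm(60, 0, 0.2), # separated
    rnorm(60, 0, 0.1),
    rnorm(60, 0, 0.05),
    rep(c(-9, 0, 9), each = 20)             # hugely separated but low VE rank
  )
  model <- structure(list(
    scores = scores,
    variance_explained = c(0.30, 0.25, 0.15, 0.05, 0.03, 0.01),
    loadings = matrix(1, 2, 6), gene_ids = c("g1", "g2")
  ), class = "nnpca_model")
  ranked <- select_em_pcs(model, labels, n_candidates = 5)
  expect_setequal(ranked, 1:5)        # component 6 not a candidate
  expect_identical(ranked[1], 3L)     # best subtype separation among top 5

  # single component is returned as-is
  m1 <- structure(list(scores = scores[, 1, drop = FALSE],
                       variance_explained = 0.3), class = "nnpca_model")
  expect_identical(select_em_pcs(m1, labels), 1L)

  # ties in subtype-mean variance break by variance explained, then index
  m2 <- structure(list(scores = cbind(scores[, 3], scores[, 3], scores[, 3]),
                       variance_explained = c(0.2, 0.3, 0.3)),
                  class = "nnpca_model")
  expect_identical(select_em_pcs(m2, labels, n_candidates = 3), c(2L, 3L, 1L))

  expect_error(select_em_pcs(m1, rep("A", 60)), "two subtypes")
})

test_that("a split mesenchymal program spreads variance over two components", {
  # one coherent E program vs two orthogonal M programs: the leading E
  # component should explain more variance than the leading M component,
  # and the two M components should be comparable
  d <- simulate_dataset(small_config(seed = 31))
  eml <- log1p_transform(normalize_total(d$expression))
  gs <- d$ground_truth$gene_sets
  fe <- nnpca_fit(eml, gs$E, n_components = 2)
  fm <- nnpca_fit(eml, gs$M, n_components = 2)
  expect_gt(fe$variance_explained[1], fm$variance_explained[1])
  expect_gt(fm$variance_explained[2] / fm$variance_explained[1], 0.3)
})
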