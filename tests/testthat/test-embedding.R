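test_that("classical MDS recovers collinear points exactly", {
  D <- as.matrix(dist(c(0, 1, 2)))
  emb <- classical_mds(D, d = 1)
  gaps <- abs(diff(emb$points[, 1]))
  expect_equal(unname(gaps), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(emb$points))), 1e-10)
})

test_that("classical MDS reproduces any Euclidean distance matrix at full rank", {
  set.seed(141)
  X <- matrix(rnorm(8 * 4), 8, 4)
  D <- as.matrix(dist(X))
  expect_warning(emb <- classical_mds(D, d = 7),  # truncates to rank 4
                 class = "qm_reduced_dimension")
  expect_lt(max(abs(embedding_distances(emb) - D)), 1e-9)
  expect_lt(max(abs(colMeans(emb$points))), 1e-10)
  expect_true(all(diff(emb$eig) <= 1e-9))  # descending spectrum
  # independent route: eigenvalues agree with stats::cmdscale
  cm <- stats::cmdscale(D, k = 4, eig = TRUE)
  expect_equal(emb$eig, cm$eig, tolerance = 1e-9)
  expect_lt(max(abs(embedding_distances(emb$points[, 1:4]) -
                    embedding_distances(cm$points))), 1e-9)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  Z <- matrix(0, 4, 4)
  expect_warning(emb <- classical_mds(Z, d = 2), class = "qm_reduced_dimension")
  expect_true(all(emb$points == 0))
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(asym, d = 1), class = "qm_validation_error")
  D <- as.matrix(dist(c(0, 1, 2)))
  expect_error(classical_mds(D, d = 3), class = "qm_domain_error")
})

test_that("Fisher distance matrices expose negative eigenvalues in the spectrum", {
  spec <- curve_spec(1, 2, 2, 3)
  joints <- lapply(seq(0, 1, length.out = 8), curve_distribution, spec = spec)
  D <- distance_matrix_joint(joints)
  emb <- suppressWarnings(classical_mds(D, d = 7))
  tol <- max(abs(emb$eig)) * 1e-10
  expect_true(any(emb$eig < -tol))   # great-circle distances are non-Euclidean
  expect_gte(scree(emb)$n_negative, 1L)
  expect_true(emb$d <= sum(emb$eig > tol))
})

test_that("embedding misfit is non-increasing in the dimension", {
  set.seed(151)
  groups <- lapply(1:8, function(k) random_marginals(3, 3, paste0("g", k)))
  D <- distance_matrix_factorized(groups)
  stress <- vapply(1:7, function(d) {
    emb <- suppressWarnings(classical_mds(D, d = d))
    sqrt(sum((embedding_distances(emb) - D)^2))
  }, numeric(1))
  expect_true(all(diff(stress) <= 1e-9))
})

test_that("rigid motions of the embedding preserve pairwise distances", {
  set.seed(161)
  groups <- lapply(1:6, function(k) random_marginals(2, 3, paste0("g", k)))
  emb <- classical_mds(distance_matrix_factorized(groups), d = 2)
  theta <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_lt(max(abs(embedding_distances(emb$points %*% R) -
                    embedding_distances(emb))), 1e-12)
})

test_that("scree suggests the elbow by largest second difference", {
  expect_equal(scree(c(10, 1e-12))$suggestion, 1L)
  flat <- scree(rep(3, 5))
  expect_true(flat$flat)
  expect_equal(flat$suggestion, 5L)
  s <- scree(c(5, 4, 0.1, 0.05))
  expect_equal(s$suggestion, 2L)
  expect_false(s$flat)
  expect_equal(s$cumulative_share, cumsum(c(5, 4, 0.1, 0.05)) / 9.15,
               tolerance = 1e-12)
})

test_that("PCA reduction matches an independent covariance eigendecomposition", {
  set.seed(171)
  X <- matrix(rnorm(5 * 4), 5, 4)
  red <- pca_reduce(X, target = 2)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(red$variance_retained,
               sum(ev$values[1:2]) / sum(ev$values), tolerance = 1e-10)
  # scores agree with direct projection up to per-column sign
  Xc <- scale(X, scale = FALSE)
  proj <- Xc %*% ev$vectors[, 1:2]
  for (j in 1:2)
    expect_true(max(abs(red$points[, j] - proj[, j])) < 1e-10 ||
                max(abs(red$points[, j] + proj[, j])) < 1e-10)

  expect_equal(pca_reduce(X, target = 4)$variance_retained, 1, tolerance = 1e-12)
  rank1 <- outer(1:5, c(1, 2))
  expect_equal(pca_reduce(rank1, target = 1)$variance_retained, 1,
               tolerance = 1e-12)
  expect_error(pca_reduce(X, target = 5), class = "qm_dimension_error")
})

test_that("Procrustes alignment undoes similarity transforms exactly", {
  set.seed(181)
  X <- matrix(rnorm(12 * 2), 12, 2)
  theta <- 1.1
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 2.5 * X %*% R + matrix(c(3, -1), 12, 2, byrow = TRUE)
  fit <- procrustes_align(Y, X)
  expect_lt(fit$disparity, 1e-12)
  expect_lt(max(abs(fit$aligned - X)), 1e-9)
  expect_lt(procrustes_align(X, X)$disparity, 1e-12)
  expect_lt(procrustes_align(X %*% diag(c(-1, 1)), X)$disparity, 1e-12)
  expect_error(procrustes_align(X, matrix(1, 12, 2)),
               class = "qm_degenerate_target")
})

test_that("Procrustes matches the closed-form orthogonal solution", {
  set.seed(191)
  X <- matrix(rnorm(10 * 3), 10, 3)
  Y <- matrix(rnorm(10 * 3), 10, 3)
  fit <- procrustes_align(Y, X)
  # oracle: center both, SVD of cross-product, optimal scale, residual
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  A <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(Yc^2)
  resid <- sum((s * Yc %*% A - Xc)^2)
  expect_equal(fit$disparity, resid / sum(Xc^2), tolerance = 1e-12)
  expect_lt(max(abs(fit$aligned - (s * Yc %*% A +
    matrix(colMeans(X), 10, 3, byrow = TRUE)))), 1e-10)
})
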