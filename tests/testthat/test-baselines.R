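test_that("correlation dissimilarity matches a direct Pearson oracle", {
  set.seed(21)
  inst <- random_fc_instance(5, 2, seed = 4)
  d <- correlation_dissimilarity(inst$A)
  A <- unclass(inst$A)
  for (i in 1:4) for (j in (i + 1):5) {
    keep <- setdiff(1:5, c(i, j))
    expect_equal(d[i, j], 1 - cor(A[i, keep], A[j, keep]), tolerance = 1e-12)
  }
  expect_equal(diag(unclass(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 2))

  # identical profiles (after excluding the forced coordinates) -> distance 0
  M <- diag(5)
  vals <- c(0.7, -0.1, 0.3)
  M[1, 3:5] <- M[3:5, 1] <- vals
  M[2, 3:5] <- M[3:5, 2] <- vals
  M[1, 2] <- M[2, 1] <- 0.5
  M[3, 4] <- M[4, 3] <- 0.2; M[3, 5] <- M[5, 3] <- -0.3
  M[4, 5] <- M[5, 4] <- 0.05
  d2 <- correlation_dissimilarity(fc_matrix(M))
  expect_equal(d2[1, 2], 0, tolerance = 1e-12)

  # constant profile is a data error naming the ROI
  C <- matrix(0.4, 5, 5); diag(C) <- 1
  expect_error(correlation_dissimilarity(fc_matrix(C)), "ROI 1")
})

test_that("graph Laplacian has zero row sums, the complete-graph spectrum, and is PSD", {
  set.seed(3)
  inst <- random_fc_instance(8, 2, seed = 6)
  S <- similarity_from_dissimilarity(correlation_dissimilarity(inst$A))
  L <- graph_laplacian(S)
  expect_equal(rowSums(L), rep(0, 8), tolerance = 1e-12)
  expect_equal(L, t(L))
  expect_gte(min(eigen(L, symmetric = TRUE)$values), -1e-10)

  # constant off-diagonal similarity s: L = s (n I - J), eigenvalues {0, ns, ns}
  s <- 0.37
  Sc <- matrix(s, 3, 3); diag(Sc) <- 1
  class(Sc) <- c("similarity_matrix", "matrix")
  ev <- sort(eigen(graph_laplacian(Sc), symmetric = TRUE)$values)
  expect_equal(ev, c(0, 3 * s, 3 * s), tolerance = 1e-12)
})

test_that("similarity transform stays within its analytic range", {
  set.seed(5)
  D <- random_dissimilarity(7)
  class(D) <- c("dissimilarity_matrix", "matrix")
  S <- similarity_from_dissimilarity(D)
  expect_true(all(S >= exp(-4) & S <= 1))
  expect_equal(diag(unclass(S)), rep(1, 7))
})

test_that("spectral clustering recovers near-disconnected blocks and is equivariant", {
  z <- make_planted_partition(c(12, 8))
  mu <- matrix(c(0.7, -0.02, -0.02, 0.7), 2, 2)
  A <- sample_fc_matrix(z, block_params(mu, matrix(0.03^2, 2, 2)), seed = 2)
  zhat <- spectral_fit(A, 2, seed = 1)
  expect_equal(nmi(z, zhat), 1)

  expect_equal(as.integer(spectral_fit(A, 1)), rep(1L, 20))

  # permuting ROI order permutes the labels (up to label names)
  perm <- sample(20)
  Ap <- fc_matrix(unclass(A)[perm, perm])
  zp <- spectral_fit(Ap, 2, seed = 1)
  expect_equal(hamming_distance(zp, fc_partition(as.integer(zhat)[perm],
                                                 K = 2))$distance, 0)
})

test_that("correlation K-means separates exact row patterns and handles K=1", {
  # two exact copies of two distinct patterns -> perfect split, objective 0
  base <- diag(4)
  base[1, 2] <- base[2, 1] <- 1     # rows 1 and 2 identical: (1,1,.1,.1)
  base[3, 4] <- base[4, 3] <- 1     # rows 3 and 4 identical: (.1,.1,1,1)
  base[1, 3] <- base[3, 1] <- base[1, 4] <- base[4, 1] <- 0.1
  base[2, 3] <- base[3, 2] <- base[2, 4] <- base[4, 2] <- 0.1
  A <- fc_matrix(base)
  zhat <- kmeans_fit(A, 2, seed = 1)
  expect_equal(nmi(fc_partition(c(1, 1, 2, 2)), zhat), 1)
  expect_lt(attr(zhat, "objective"), 1e-10)

  z1 <- kmeans_fit(A, 1, seed = 1)
  expect_equal(as.integer(z1), rep(1L, 4))
})

test_that("correlation K-means recovers planted blocks at strong signal", {
  z <- make_planted_partition(c(15, 15))
  mu <- matrix(0, 2, 2); diag(mu) <- 0.6
  A <- sample_fc_matrix(z, block_params(mu, matrix(0.05^2, 2, 2)), seed = 3)
  hits <- sum(vapply(1:100, function(s)
    nmi(z, kmeans_fit(A, 2, seed = s)) == 1, logical(1)))
  expect_gte(hits, 95)
  expect_error(kmeans_fit(A, 31), "K")
})

test_that("K-means objective trace never increases within the winning restart", {
  set.seed(77)
  for (r in 1:5) {
    inst <- random_fc_instance(20, 3, seed = 40 + r)
    zf <- kmeans_fit(inst$A, 3, seed = r)
    trace <- attr(zf, "objective_trace")
    if (length(trace) > 1) expect_gte(min(-diff(trace)), -1e-9)
  }
})

test_that("baseline fits are deterministic given their seed", {
  inst <- random_fc_instance(15, 3, seed = 12)
  expect_identical(as.integer(spectral_fit(inst$A, 3, seed = 5)),
                   as.integer(spectral_fit(inst$A, 3, seed = 5)))
  expect_identical(as.integer(kmeans_fit(inst$A, 3, seed = 5)),
                   as.integer(kmeans_fit(inst$A, 3, seed = 5)))
})

test_that("all three methods agree at the strong-signal benchmark", {
  sim <- simulate_connectome(signal = "strong", seed = 8)
  zw <- map_labels(best_fit(fit_ensemble(sim$A, 5, n_runs = 10,
                                         base_seed = 1)))
  zs <- spectral_fit(sim$A, 5, seed = 1)
  zk <- kmeans_fit(sim$A, 5, seed = 1)
  expect_gte(nmi(zw, zs), 0.9)
  expect_gte(nmi(zw, zk), 0.9)
  expect_gte(nmi(zs, zk), 0.9)
})
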