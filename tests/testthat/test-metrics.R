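test_that("silhouette matches hand computations on block-constant distances", {
  # two 2-point blocks, within-d 0.1, between-d 1.0 -> every score 0.9
  D <- matrix(1, 4, 4)
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 0.1
  diag(D) <- 0
  z <- fc_partition(c(1, 1, 2, 2))
  expect_equal(silhouette_index(D, z), 0.9, tolerance = 1e-12)

  # all distances equal -> a == b everywhere -> 0
  De <- matrix(0.5, 6, 6); diag(De) <- 0
  expect_equal(silhouette_index(De, fc_partition(rep(1:2, 3))), 0)

  # shuffling a block structure can only lower the score
  set.seed(10)
  zb <- fc_partition(rep(1:2, each = 5))
  Db <- matrix(1, 10, 10)
  for (k in 0:1) Db[1:5 + 5 * k, 1:5 + 5 * k] <- 0.2
  diag(Db) <- 0
  shuffled <- fc_partition(sample(as.integer(zb)))
  expect_lt(silhouette_index(Db, shuffled), silhouette_index(Db, zb))

  expect_error(silhouette_index(D, fc_partition(rep(1, 4))), "two communities")
})

test_that("silhouette agrees with the cluster package on random instances", {
  skip_if_not_installed("cluster")
  set.seed(14)
  for (r in 1:5) {
    n <- sample(8:14, 1)
    D <- random_dissimilarity(n)
    z <- sample.int(3, n, replace = TRUE)
    z[1:3] <- 1:3
    ours <- silhouette_index(D, fc_partition(z))
    ref <- mean(cluster::silhouette(z, dmatrix = D)[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("modularity matches closed cases and a double-loop oracle", {
  # one community: identically zero
  set.seed(2)
  inst <- random_fc_instance(6, 2, seed = 3)
  expect_equal(modularity_index(inst$A, fc_partition(rep(1, 6))), 0,
               tolerance = 1e-12)

  # two disjoint dyads: Q = 1/2
  M <- diag(4)
  M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- 1
  expect_equal(modularity_index(fc_matrix(M), fc_partition(c(1, 1, 2, 2))),
               0.5, tolerance = 1e-12)

  for (r in 1:10) {
    inst <- random_fc_instance(6, 3, seed = 50 + r)
    z <- sample.int(3, 6, replace = TRUE)
    expect_equal(modularity_index(inst$A, fc_partition(z)),
                 oracle_modularity(inst$A, z), tolerance = 1e-12)
  }
})

test_that("VI distance matches entropy arithmetic and is a metric", {
  expect_equal(vi_distance(c(1, 2, 1, 2), c(1, 2, 1, 2)), 0)
  # independent balanced 2x2 table: I = 0, VI = 2 log 2
  expect_equal(vi_distance(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 * log(2),
               tolerance = 1e-12)
  set.seed(8)
  for (r in 1:20) {
    n <- sample(6:12, 1)
    z1 <- sample.int(3, n, replace = TRUE)
    z2 <- sample.int(3, n, replace = TRUE)
    z3 <- sample.int(3, n, replace = TRUE)
    expect_equal(vi_distance(z1, z2), vi_distance(z2, z1), tolerance = 1e-12)
    expect_equal(vi_distance(z1, z2), oracle_vi(z1, z2), tolerance = 1e-9)
    # triangle inequality
    expect_lte(vi_distance(z1, z3),
               vi_distance(z1, z2) + vi_distance(z2, z3) + 1e-9)
  }
})

test_that("NMI matches the contingency-table oracle and its conventions", {
  expect_equal(nmi(c(1, 2, 3, 1), c(2, 3, 1, 2)), 1)   # pure relabeling
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)   # independent table
  expect_equal(nmi(rep(1, 5), rep(1, 5)), 1)           # both trivial
  expect_equal(nmi(rep(1, 4), c(1, 2, 1, 2)), 0)       # one trivial
  set.seed(9)
  for (r in 1:20) {
    n <- sample(6:12, 1)
    z1 <- sample.int(4, n, replace = TRUE)
    z2 <- sample.int(3, n, replace = TRUE)
    expect_equal(nmi(z1, z2), oracle_nmi(z1, z2), tolerance = 1e-12)
  }
})

test_that("CH index matches its direct-sum oracle and degenerate limits", {
  # perfectly compact blocks: SSW = 0 -> infinite index
  D0 <- matrix(1, 4, 4)
  D0[1, 2] <- D0[2, 1] <- D0[3, 4] <- D0[4, 3] <- 0
  diag(D0) <- 0
  expect_equal(ch_index(D0, fc_partition(c(1, 1, 2, 2))), Inf)

  set.seed(12)
  for (r in 1:10) {
    D <- random_dissimilarity(8)
    z <- c(1, 2, 3, sample.int(3, 5, replace = TRUE))
    expect_equal(ch_index(D, fc_partition(z)), oracle_ch(D, z),
                 tolerance = 1e-10)
  }

  # merging genuinely distinct blocks lowers CH
  Db <- matrix(1, 9, 9)
  for (k in 0:2) Db[1:3 + 3 * k, 1:3 + 3 * k] <- 0.1
  diag(Db) <- 0
  z3 <- fc_partition(rep(1:3, each = 3))
  z2 <- fc_partition(c(1, 1, 1, 1, 1, 1, 2, 2, 2), K = 2)
  expect_gt(ch_index(Db, z3), ch_index(Db, z2))
  expect_error(ch_index(Db, fc_partition(rep(1, 9))), "communities")
})

test_that("C-index matches its sort-and-sum oracle and its extremes", {
  # within pairs exactly the smallest distances -> 0
  D0 <- matrix(1, 4, 4)
  D0[1, 2] <- D0[2, 1] <- D0[3, 4] <- D0[4, 3] <- 0.1
  diag(D0) <- 0
  expect_equal(c_index(D0, fc_partition(c(1, 1, 2, 2))), 0, tolerance = 1e-12)
  # within pairs exactly the largest -> 1
  expect_equal(c_index(D0, fc_partition(c(1, 2, 1, 2))), 1, tolerance = 1e-12)

  set.seed(13)
  for (r in 1:10) {
    D <- random_dissimilarity(7)
    z <- c(1, 2, sample.int(2, 5, replace = TRUE))
    expect_equal(c_index(D, fc_partition(z)), oracle_cindex(D, z),
                 tolerance = 1e-12)
  }
  expect_error(c_index(random_dissimilarity(3), fc_partition(1:3)),
               "singleton")
})

test_that("Dunn index matches block geometry and a triple-loop oracle", {
  # within-d <= 0.2, between-d >= 1.0 -> Dunn = 1.0 / 0.2 = 5
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0.2; D[4:6, 4:6] <- 0.2
  diag(D) <- 0
  expect_equal(dunn_index(D, fc_partition(rep(1:2, each = 3))), 5,
               tolerance = 1e-12)

  # duplicated points across communities -> numerator 0
  Dd <- random_dissimilarity(5)
  Dd[1, 2] <- Dd[2, 1] <- 0
  expect_equal(dunn_index(Dd, fc_partition(c(1, 2, 1, 2, 2))), 0)

  set.seed(15)
  for (r in 1:10) {
    Dr <- random_dissimilarity(8)
    z <- c(1, 1, 2, sample.int(2, 5, replace = TRUE))
    expect_equal(dunn_index(Dr, fc_partition(z)), oracle_dunn(Dr, z),
                 tolerance = 1e-12)
  }
})

test_that("Hamming distance solves the optimal relabeling exactly", {
  # pure relabeling -> 0
  z1 <- c(1, 1, 2, 2, 3)
  z2 <- c(3, 3, 1, 1, 2)
  h <- hamming_distance(fc_partition(z1), fc_partition(z2))
  expect_equal(h$distance, 0)
  expect_equal(h$permutation[z2], z1)

  # one disagreeing vertex among four
  expect_equal(hamming_distance(fc_partition(c(1, 1, 2, 2)),
                                fc_partition(c(1, 2, 2, 2)))$distance, 0.25)

  # exhaustive K! oracle on random pairs
  set.seed(16)
  for (r in 1:20) {
    n <- sample(6:12, 1)
    K <- sample(2:5, 1)
    z1 <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
    z2 <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
    got <- hamming_distance(fc_partition(z1, K), fc_partition(z2, K))$distance
    expect_equal(got, oracle_hamming(z1, z2, K), tolerance = 1e-12)
    # symmetry and relabel invariance
    expect_equal(got,
                 hamming_distance(fc_partition(z2, K),
                                  fc_partition(z1, K))$distance,
                 tolerance = 1e-12)
    perm <- sample.int(K)
    expect_equal(got,
                 hamming_distance(fc_partition(z1, K),
                                  fc_partition(perm[z2], K))$distance,
                 tolerance = 1e-12)
  }
})

test_that("index ranges hold on randomized partitions of sampled networks", {
  set.seed(19)
  for (r in 1:10) {
    inst <- random_fc_instance(10, 3, seed = 70 + r)
    D <- correlation_dissimilarity(inst$A)
    z <- fc_partition(c(1, 2, 3, sample.int(3, 7, replace = TRUE)), K = 3)
    s <- silhouette_index(D, z)
    expect_true(s >= -1 && s <= 1)
    expect_gte(vi_distance(z, inst$z), 0)
    nm <- nmi(z, inst$z)
    expect_true(nm >= 0 && nm <= 1)
    cx <- c_index(D, z)
    expect_true(cx >= 0 && cx <= 1)
    expect_gte(dunn_index(D, z), 0)
    hd <- hamming_distance(z, inst$z)$distance
    expect_true(hd >= 0 && hd <= 1)
  }
})
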