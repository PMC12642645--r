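test_that("gaussian log-likelihood matches closed forms and a pairwise oracle", {
  # n = 2, standard normal at 0: density -log(sqrt(2*pi))
  A <- fc_matrix(matrix(c(1, 0, 0, 1), 2, 2))
  z <- fc_partition(c(1, 1))
  p <- block_params(matrix(0), matrix(1))
  expect_equal(gaussian_loglik(A, z, p), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # zero residuals: only the normalization terms remain
  z3 <- fc_partition(c(1, 1, 2))
  mu <- matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2)
  s2 <- matrix(c(0.04, 0.02, 0.02, 0.09), 2, 2)
  M <- diag(3)
  zi <- as.integer(z3)
  for (i in 1:2) for (j in (i + 1):3) M[i, j] <- M[j, i] <- mu[zi[i], zi[j]]
  A3 <- fc_matrix(M)
  expected <- 0
  for (i in 1:2) for (j in (i + 1):3)
    expected <- expected - 0.5 * log(2 * pi * s2[zi[i], zi[j]])
  expect_equal(gaussian_loglik(A3, z3, block_params(mu, s2)), expected,
               tolerance = 1e-12)

  # random 5-node instances against the brute-force oracle
  set.seed(42)
  for (r in 1:10) {
    inst <- random_fc_instance(5, 2, seed = r)
    expect_equal(
      gaussian_loglik(inst$A, inst$z, inst$params),
      oracle_gaussian_loglik(unclass(inst$A), as.integer(inst$z),
                             inst$params$mu, inst$params$sigma2),
      tolerance = 1e-10)
  }
  expect_no_error(gaussian_loglik(A, z, block_params(matrix(0),
                                                     matrix(1e-12))))
})

test_that("joint log density decomposes into likelihood, label and parameter priors", {
  inst <- random_fc_instance(4, 2, seed = 5)
  pr <- wsbm_prior()
  base <- gaussian_loglik(inst$A, inst$z, inst$params)
  # flat label prior only
  expect_equal(joint_log_density(inst$A, inst$z, inst$params, pr,
                                 include_param_prior = FALSE),
               base + 4 * log(1 / 2), tolerance = 1e-12)
  # flat-prior contribution for n = 100, K = 5
  expect_equal(100 * log(1 / 5), -160.9438, tolerance = 1e-4)
  # term-by-term oracle for the normal-inverse-gamma parameter prior
  lp <- 0
  for (a in 1:2) for (b in a:2) {
    mu <- inst$params$mu[a, b]; s2 <- inst$params$sigma2[a, b]
    lp <- lp + dnorm(mu, pr$m0, sqrt(s2 / pr$kappa0), log = TRUE) +
      pr$alpha0 * log(pr$beta0) - lgamma(pr$alpha0) -
      (pr$alpha0 + 1) * log(s2) - pr$beta0 / s2
  }
  expect_equal(joint_log_density(inst$A, inst$z, inst$params, pr),
               base + 4 * log(1 / 2) + lp, tolerance = 1e-10)
})

test_that("single-component fit collapses to the shrunk grand mean", {
  inst <- random_fc_instance(12, 2, seed = 9)
  f <- vb_fit(inst$A, 1, seed = 1)
  expect_equal(as.numeric(f$responsibilities), rep(1, 12))
  w <- unclass(inst$A)[upper.tri(inst$A)]
  pr <- wsbm_prior()
  shrunk <- (pr$kappa0 * pr$m0 + sum(w)) / (pr$kappa0 + length(w))
  expect_equal(f$block_params$mu[1, 1], shrunk, tolerance = 1e-8)
})

test_that("responsibility rows are distributions and MAP labels break ties low", {
  inst <- random_fc_instance(20, 3, seed = 2)
  f <- vb_fit(inst$A, 3, seed = 7)
  expect_true(all(f$responsibilities >= 0 & f$responsibilities <= 1))
  expect_lt(max(abs(rowSums(f$responsibilities) - 1)), 1e-8)

  fake <- list(responsibilities = rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0),
                                        c(0, 0, 1)),
               K_input = 3L)
  expect_equal(as.integer(map_labels(fake)), c(2L, 1L, 3L))
  onehot <- list(responsibilities = diag(3)[c(3, 1, 2), ], K_input = 3L)
  expect_equal(as.integer(map_labels(onehot)), c(3L, 1L, 2L))
})

test_that("solution validity counts distinct labels against the requested K", {
  expect_true(is_valid_solution(c(1, 2, 3, 1, 2, 3), 3))
  expect_false(is_valid_solution(c(1, 1, 1, 1), 2))
  expect_true(is_valid_solution(c(1, 2), 2))
})

test_that("variational objective is non-decreasing for both update schemes", {
  set.seed(31)
  worst <- Inf
  for (r in 1:25) {
    n <- sample(10:25, 1)
    K <- sample(2:4, 1)
    inst <- random_fc_instance(n, K, seed = 200 + r)
    for (m in c("vem", "vb")) {
      f <- vb_fit(inst$A, K, seed = r, method = m)
      if (f$n_iter > 1) worst <- min(worst, diff(f$objective_trace))
    }
  }
  expect_gte(worst, -1e-6)
})

test_that("strong-signal two-block structure is recovered in nearly every run", {
  z <- make_planted_partition(c(20, 20))
  mu <- matrix(0, 2, 2); diag(mu) <- 0.6
  A <- sample_fc_matrix(z, block_params(mu, matrix(0.05^2, 2, 2)), seed = 42)
  hits <- sum(vapply(1:100, function(s)
    nmi(z, map_labels(vb_fit(A, 2, seed = s))) == 1, logical(1)))
  expect_gte(hits, 95)
})

test_that("posterior block means recover the truth on strong-signal data", {
  K <- 5
  mu <- matrix(0, K, K); diag(mu) <- 0.6
  truth <- block_params(mu, matrix(0.1^2, K, K))
  z <- make_planted_partition(c(30, 15, 25, 20, 10))
  A <- sample_fc_matrix(z, truth, seed = 17)
  f <- best_fit(fit_ensemble(A, K, n_runs = 10, base_seed = 1))
  perm <- hamming_distance(z, map_labels(f))$permutation
  expect_lt(max(abs(f$block_params$mu[perm, perm] - mu)), 0.05)
})

test_that("relabeling the initialization permutes the fit equivariantly", {
  inst <- random_fc_instance(15, 3, seed = 3)
  A0 <- unclass(inst$A); diag(A0) <- 0
  set.seed(4)
  g <- matrix(rexp(15 * 3), 15, 3); R0 <- g / rowSums(g)
  perm <- c(3L, 1L, 2L)
  f1 <- fccomm:::vb_cavi(A0, R0, 0, 1, 2, 0.1, 200L, 1e-6, TRUE)
  f2 <- fccomm:::vb_cavi(A0, R0[, perm], 0, 1, 2, 0.1, 200L, 1e-6, TRUE)
  # column b of the permuted run equals column perm[b] of the original
  expect_equal(f2$responsibilities, f1$responsibilities[, perm],
               tolerance = 1e-8)
  expect_equal(f2$mu, f1$mu[perm, perm], tolerance = 1e-8)
  expect_equal(tail(f2$objective_trace, 1), tail(f1$objective_trace, 1),
               tolerance = 1e-8)
})

test_that("ensembles keep only valid runs, reproducibly, and survive degeneracy", {
  z <- make_planted_partition(c(20, 20))
  mu <- matrix(0, 2, 2); diag(mu) <- 0.6
  A <- sample_fc_matrix(z, block_params(mu, matrix(0.05^2, 2, 2)), seed = 42)
  p1 <- fit_ensemble(A, 2, n_runs = 1, base_seed = 3)
  expect_length(p1$fits, 1)
  expect_identical(p1$loglik,
                   fit_ensemble(A, 2, n_runs = 1, base_seed = 3)$loglik)

  # K = n on a tiny instance: few or no valid runs, no crash
  inst <- random_fc_instance(4, 2, seed = 8)
  p4 <- fit_ensemble(inst$A, 4, n_runs = 5, base_seed = 1)
  expect_s3_class(p4, "wsbm_pool")
  expect_equal(length(p4$fits) + p4$n_discarded, 5L)
})

test_that("degenerate and invalid inputs are rejected", {
  inst <- random_fc_instance(6, 2, seed = 1)
  expect_error(vb_fit(inst$A, 7), "K")
  B <- unclass(inst$A); B[1, 2] <- B[2, 1] <- NA
  expect_error(vb_fit(fc_matrix(B, check = FALSE), 2), "non-finite")
  expect_error(wsbm_prior(kappa0 = 0), "kappa0")
})
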