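# Brute-force oracles, independent of the package's implementation paths.
# All loop pair by pair / cell by cell and are only used on tiny instances.

oracle_gaussian_loglik <- function(A, z, mu, sigma2) {
  n <- nrow(A)
  out <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- out + dnorm(A[i, j], mu[z[i], z[j]], sqrt(sigma2[z[i], z[j]]),
                       log = TRUE)
  }
  out
}

oracle_modularity <- function(A, z) {
  A <- unclass(A); diag(A) <- 0
  n <- nrow(A)
  two_m <- sum(A)
  d <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (z[i] == z[j]) q <- q + A[i, j] - d[i] * d[j] / two_m
  }
  q / two_m
}

oracle_entropy <- function(z) {
  p <- table(z) / length(z)
  -sum(p * log(p))
}

oracle_mutual_information <- function(z1, z2) {
  n <- length(z1)
  I <- 0
  for (a in unique(z1)) for (b in unique(z2)) {
    pab <- sum(z1 == a & z2 == b) / n
    if (pab > 0)
      I <- I + pab * log(pab / ((sum(z1 == a) / n) * (sum(z2 == b) / n)))
  }
  I
}

oracle_vi <- function(z1, z2) {
  oracle_entropy(z1) + oracle_entropy(z2) - 2 * oracle_mutual_information(z1, z2)
}

oracle_nmi <- function(z1, z2) {
  h1 <- oracle_entropy(z1); h2 <- oracle_entropy(z2)
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  oracle_mutual_information(z1, z2) / sqrt(h1 * h2)
}

oracle_ch <- function(D, z) {
  n <- length(z)
  K <- length(unique(z))
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (k in unique(z)) {
    idx <- which(z == k)
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        ssw <- ssw + D[idx[a], idx[b]]^2 / length(idx)
  }
  if (ssw == 0) return(Inf)
  ((sst - ssw) / (K - 1)) / (ssw / (n - K))
}

oracle_cindex <- function(D, z) {
  n <- length(z)
  dvals <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dvals <- c(dvals, D[i, j])
    within <- c(within, z[i] == z[j])
  }
  nw <- sum(within)
  sw <- sum(dvals[within])
  s <- sort(dvals)
  smin <- sum(s[seq_len(nw)])
  smax <- sum(rev(s)[seq_len(nw)])
  (sw - smin) / (smax - smin)
}

oracle_dunn <- function(D, z) {
  labs <- unique(z)
  diam <- 0
  for (k in labs) {
    idx <- which(z == k)
    if (length(idx) > 1)
      for (a in idx) for (b in idx) diam <- max(diam, D[a, b])
  }
  sep <- Inf
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (a < b)
      for (i in which(z == labs[a])) for (j in which(z == labs[b]))
        sep <- min(sep, D[i, j])
  }
  sep / diam
}

# exhaustive K! search over label permutations of z2
oracle_hamming <- function(z1, z2, K) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- Inf
  for (p in perms(seq_len(K))) {
    best <- min(best, mean(z1 != p[z2]))
  }
  best
}

# random dissimilarity matrix (symmetric, zero diagonal, entries in [0, 2])
random_dissimilarity <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 2)
  D + t(D)
}

# small random FC matrix with planted labels
random_fc_instance <- function(n, K, seed) {
  z <- fc_partition(c(seq_len(K), sample.int(K, n - K, replace = TRUE)),
                    K = K)
  params <- make_block_params(K, seed = seed)
  list(A = sample_fc_matrix(z, params, seed = seed + 1L), z = z,
       params = params)
}
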