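#' Silhouette coefficient of a partition
#'
#' Mean over vertices of `(b - a) / max(a, b)`, where `a` is the average
#' dissimilarity of a vertex to the other members of its own community and
#' `b` the smallest average dissimilarity to any other community. Vertices
#' in singleton communities score 0 (their `a` is undefined; the usual
#' convention). Range `[-1, 1]`; higher is better.
#'
#' @param D A symmetric dissimilarity matrix with zero diagonal (e.g.
#'   [correlation_dissimilarity()]).
#' @param z An [fc_partition()] using at least two communities.
#' @return Scalar silhouette coefficient.
#' @export
silhouette_index <- function(D, z) {
  z <- as.integer(z)
  n <- length(z)
  labs <- sort(unique(z))
  if (length(labs) < 2L)
    stop("silhouette_index: needs at least two communities")
  D <- unclass(D)
  sizes <- tabulate(z, max(labs))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- z[i]
    if (sizes[k] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, z == k]) / (sizes[k] - 1L)  # D[i,i] = 0 drops out
    b <- min(vapply(labs[labs != k],
                    function(ss) mean(D[i, z == ss]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Weighted modularity of a partition
#'
#' `Q = 1/(2m) * sum_{i,j} (A_ij - d_i d_j / (2m)) 1{z_i = z_j}` over all
#' ordered pairs including i = j, with `m = 1/2 sum_{i,j} A_ij` and degrees
#' `d_i = sum_{j != i} A_ij`. The unit self-weights are removed before
#' computing m and the degrees (`zero_diag = TRUE`): they are an artifact of
#' the correlation diagonal and the null model assumes self-loop-free
#' degrees. Negative edge weights enter as-is.
#'
#' @param A An [fc_matrix()].
#' @param z An [fc_partition()].
#' @param zero_diag Remove the diagonal before computing m and degrees.
#' @return Scalar modularity.
#' @export
modularity_index <- function(A, z, zero_diag = TRUE) {
  z <- as.integer(z)
  A0 <- unclass(A)
  if (zero_diag) diag(A0) <- 0
  two_m <- sum(A0)
  if (two_m == 0) stop("modularity_index: total edge weight is zero")
  d <- rowSums(A0)
  same <- outer(z, z, `==`)
  sum((A0 - outer(d, d) / two_m)[same]) / two_m
}

# contingency proportions and entropies shared by VI / NMI
partition_information <- function(z1, z2) {
  z1 <- as.integer(z1); z2 <- as.integer(z2)
  if (length(z1) != length(z2))
    stop("partition comparison: label vectors differ in length")
  n <- length(z1)
  P <- table(z1, z2) / n
  p1 <- rowSums(P); p2 <- colSums(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pp <- as.numeric(P); pe <- as.numeric(outer(p1, p2))
  nz <- pp > 0
  list(H1 = H(p1), H2 = H(p2), I = sum(pp[nz] * log(pp[nz] / pe[nz])))
}

#' Variation of information between two partitions
#'
#' The entropy-based distance `VI = H(z1) + H(z2) - 2 I(z1, z2)` (natural
#' logarithms). It is a metric on partitions: zero iff the two partitions
#' are identical up to relabeling.
#'
#' @param z1,z2 Partitions of the same vertex set.
#' @return Scalar VI distance (>= 0).
#' @export
vi_distance <- function(z1, z2) {
  pi_ <- partition_information(z1, z2)
  max(0, pi_$H1 + pi_$H2 - 2 * pi_$I)
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(z1, z2) / sqrt(H(z1) H(z2))` (geometric-mean normalization,
#' natural logarithms). Two single-community partitions have NMI 1; if only
#' one partition is trivial the NMI is 0.
#'
#' @param z1,z2 Partitions of the same vertex set.
#' @param normalization `"geometric"` (default) or `"arithmetic"`
#'   (`2 I / (H1 + H2)`).
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(z1, z2, normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  pi_ <- partition_information(z1, z2)
  if (pi_$H1 == 0 && pi_$H2 == 0) return(1)
  denom <- if (normalization == "geometric") sqrt(pi_$H1 * pi_$H2)
           else (pi_$H1 + pi_$H2) / 2
  if (denom == 0) return(0)
  min(1, max(0, pi_$I / denom))
}

#' Calinski-Harabasz pseudo-F index on dissimilarities
#'
#' `CH = (SSA / (K - 1)) / (SSW / (n - K))` where
#' `SSW = sum_k (1/n_k) sum_{i<j in C_k} d_ij^2`,
#' `SST = (1/n) sum_{i<j} d_ij^2` and `SSA = SST - SSW`. Higher indicates
#' more compact, better-separated communities. Perfectly compact
#' communities (SSW = 0) return `Inf`.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param z An [fc_partition()] with 2 <= K <= n - 1 communities in use.
#' @return Scalar CH index.
#' @export
ch_index <- function(D, z) {
  z <- as.integer(z)
  n <- length(z)
  labs <- unique(z)
  K <- length(labs)
  if (K < 2L || K > n - 1L)
    stop("ch_index: number of communities must be in [2, n-1]")
  D2 <- unclass(D)^2
  ut <- upper.tri(D2)
  sst <- sum(D2[ut]) / n
  ssw <- 0
  for (k in labs) {
    idx <- which(z == k)
    if (length(idx) > 1L)
      ssw <- ssw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  ssa <- sst - ssw
  if (ssw == 0) return(Inf)
  (ssa / (K - 1)) / (ssw / (n - K))
}

#' C-index of a partition
#'
#' `C = (SW - Smin) / (Smax - Smin)` where SW is the sum of within-community
#' pairwise dissimilarities, and Smin/Smax are the sums of the NW smallest
#' and largest dissimilarities among all pairs, with NW the number of
#' within-community pairs. Range `[0, 1]`; lower is better.
#'
#' @inheritParams ch_index
#' @return Scalar C-index.
#' @export
c_index <- function(D, z) {
  z <- as.integer(z)
  n <- length(z)
  D <- unclass(D)
  ut <- which(upper.tri(D))
  same <- outer(z, z, `==`)[ut]
  nw <- sum(same)
  if (nw == 0L) stop("c_index: no within-community pairs (all singletons)")
  if (nw == length(ut)) stop("c_index: all pairs within one community")
  dvals <- D[ut]
  sw <- sum(dvals[same])
  sorted <- sort(dvals)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (smax == smin) stop("c_index: degenerate (all distances equal)")
  (sw - smin) / (smax - smin)
}

#' Dunn index of a partition
#'
#' Minimum single-linkage distance between two communities divided by the
#' maximum community diameter. Higher indicates compact, well-separated
#' communities.
#'
#' @inheritParams ch_index
#' @return Scalar Dunn index (>= 0).
#' @export
dunn_index <- function(D, z) {
  z <- as.integer(z)
  labs <- sort(unique(z))
  K <- length(labs)
  if (K < 2L) stop("dunn_index: needs at least two communities")
  D <- unclass(D)
  diam <- 0
  for (k in labs) {
    idx <- which(z == k)
    if (length(idx) > 1L)
      diam <- max(diam, max(D[idx, idx]))
  }
  if (diam == 0) stop("dunn_index: all community diameters are zero")
  sep <- Inf
  for (a in seq_len(K - 1L)) for (b in seq.int(a + 1L, K)) {
    sep <- min(sep, min(D[z == labs[a], z == labs[b]]))
  }
  sep / diam
}

# Hungarian algorithm (Kuhn-Munkres, shortest augmenting path with
# potentials, O(K^3)) for a square min-cost assignment. Returns for each
# column the assigned row.
solve_assignment <- function(cost) {
  nK <- nrow(cost)
  stopifnot(ncol(cost) == nK)
  INF <- .Machine$double.xmax / 4
  u <- numeric(nK + 1L); v <- numeric(nK + 1L)
  p <- integer(nK + 1L)  # p[j]: row assigned to column j (0 = none)
  way <- integer(nK + 1L)
  for (i in seq_len(nK)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, nK + 1L)
    used <- rep(FALSE, nK + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(nK)) {
        jj <- j + 1L
        if (!used[jj]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(nK + 1L)) {
        if (used[jj]) {
          if (p[jj] > 0L) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(nK)
  for (j in seq_len(nK)) assignment[j] <- p[j + 1L]
  assignment  # assignment[j] = row matched to column j
}

#' Hamming distance between partitions with optimal relabeling
#'
#' The minimum fraction of disagreeing labels over all permutations of the
#' second partition's labels: a K x K agreement (confusion) matrix is
#' built and the match-maximizing permutation found with the Hungarian
#' assignment algorithm.
#'
#' @param z1,z2 Partitions of the same vertex set with labels in `{1..K}`.
#' @return List with `distance` (mismatch proportion in `[0, 1]`) and
#'   `permutation` (integer vector: `permutation[b]` is the label in z1
#'   space assigned to label b of z2).
#' @export
hamming_distance <- function(z1, z2) {
  K <- max(partition_k(z1), partition_k(z2))
  z1 <- as.integer(z1); z2 <- as.integer(z2)
  if (length(z1) != length(z2))
    stop("hamming_distance: label vectors differ in length")
  n <- length(z1)
  M <- matrix(0, K, K)
  for (i in seq_len(n)) M[z1[i], z2[i]] <- M[z1[i], z2[i]] + 1
  perm <- solve_assignment(-M)  # maximize agreements
  matches <- sum(M[cbind(perm, seq_len(K))])
  list(distance = 1 - matches / n, permutation = perm)
}
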