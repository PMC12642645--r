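#' Correlation dissimilarity between connectivity profiles
#'
#' `d[i, j] = 1 - cor(row_i(A), row_j(A))`, the standard dissimilarity
#' between the connectivity profiles of two ROIs. By default the
#' coordinates i and j are excluded from each pairwise correlation: a
#' symmetric matrix with unit diagonal forces `A[i, i] = A[j, j] = 1`, and
#' those entries would bias the profile correlation.
#'
#' @param A An [fc_matrix()] with n >= 3.
#' @param exclude_self Drop coordinates i and j from the correlation of
#'   rows i and j.
#' @return A symmetric n x n matrix with zero diagonal and entries in
#'   `[0, 2]` (class `dissimilarity_matrix`).
#' @export
correlation_dissimilarity <- function(A, exclude_self = TRUE) {
  n <- nrow(A)
  if (n < 3L)
    stop("correlation_dissimilarity: need n >= 3")
  Araw <- unclass(A)
  offdiag_sd <- vapply(seq_len(n), function(i) sd(Araw[i, -i]), numeric(1))
  if (any(offdiag_sd == 0))
    stop(sprintf(
      "correlation_dissimilarity: constant connectivity profile for ROI %d",
      which(offdiag_sd == 0)[1]))
  d <- matrix(0, n, n)
  if (exclude_self) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- cor(Araw[i, -c(i, j)], Araw[j, -c(i, j)])
        if (is.na(r))
          stop(sprintf(
            "correlation_dissimilarity: undefined correlation for ROIs %d, %d",
            i, j))
        d[i, j] <- d[j, i] <- 1 - r
      }
    }
  } else {
    r <- cor(t(Araw))
    d <- 1 - r
    diag(d) <- 0
  }
  d[] <- pmin(2, pmax(0, d))
  class(d) <- c("dissimilarity_matrix", "matrix")
  d
}

#' Gaussian similarity from a dissimilarity matrix
#'
#' `S[i, j] = exp(-d[i, j]^2)`; since d is bounded by 2, entries lie in
#' `[exp(-4), 1]` with unit diagonal.
#'
#' @param d A `dissimilarity_matrix` (or any symmetric nonnegative matrix
#'   with zero diagonal).
#' @return A symmetric similarity matrix (class `similarity_matrix`).
#' @export
similarity_from_dissimilarity <- function(d) {
  S <- exp(-unclass(d)^2)
  class(S) <- c("similarity_matrix", "matrix")
  S
}

#' Unnormalized graph Laplacian
#'
#' `L = D - S` with degrees `D_ii = sum_{j != i} S[i, j]`: the similarity
#' matrix's diagonal is excluded from the degree (equivalently, zeroed
#' before forming L), so every row of L sums to zero and L is symmetric
#' positive semidefinite.
#'
#' @param S A `similarity_matrix`.
#' @return The n x n Laplacian matrix.
#' @export
graph_laplacian <- function(S) {
  S0 <- unclass(S)
  diag(S0) <- 0
  diag(rowSums(S0)) - S0
}

#' Spectral clustering of an FC matrix
#'
#' Builds the correlation dissimilarity, the Gaussian similarity
#' `exp(-d^2)`, and the unnormalized Laplacian `L = D - S`; embeds each ROI
#' as its coordinates in the eigenvectors belonging to the K eigenvalues of
#' L smallest in absolute value; and clusters the embedded rows with
#' Euclidean K-means (multi-restart, seeded). Rows are used as-is, without
#' length normalization.
#'
#' @param A An [fc_matrix()].
#' @param K Number of communities (K <= n).
#' @param seed RNG seed for the K-means restarts.
#' @param n_restarts K-means restarts in the embedded space.
#' @param exclude_self Passed to [correlation_dissimilarity()].
#' @return An [fc_partition()].
#' @export
spectral_fit <- function(A, K, seed = 1L, n_restarts = 10L,
                         exclude_self = TRUE) {
  n <- nrow(A)
  if (K > n) stop("spectral_fit: K must be <= n")
  if (K == 1L) return(fc_partition(rep(1L, n), K = 1L))
  d <- correlation_dissimilarity(A, exclude_self = exclude_self)
  S <- similarity_from_dissimilarity(d)
  L <- graph_laplacian(S)
  eig <- tryCatch(eigen(L, symmetric = TRUE),
                  error = function(e) stop(
                    "spectral_fit: eigendecomposition failed: ",
                    conditionMessage(e)))
  sel <- order(abs(eig$values))[seq_len(K)]
  X <- eig$vectors[, sel, drop = FALSE]
  km <- with_seed(seed,
                  kmeans(X, centers = K, nstart = n_restarts, iter.max = 100L))
  fc_partition(km$cluster, K = K)
}

#' K-means on connectivity profiles under correlation dissimilarity
#'
#' Lloyd-style clustering of the rows of the FC matrix where proximity is
#' `1 - Pearson(row, centroid)`. Centroids are initialized at K distinct
#' randomly chosen rows, assignment picks the closest centroid, and
#' centroids are recomputed as arithmetic means of their member rows;
#' iteration stops when assignments stop changing (or at `max_iter`). If a
#' centroid update would increase the within-cluster dissimilarity sum
#' (possible because the arithmetic mean is only a surrogate minimizer
#' under a correlation metric), the previous assignment is kept and the
#' restart terminates, so the recorded objective never increases. An
#' emptied cluster is reseeded at the point farthest from its centroid.
#' The best of `n_restarts` runs by total within-cluster dissimilarity is
#' returned.
#'
#' @param A An [fc_matrix()].
#' @param K Number of communities (K <= n).
#' @param n_restarts Independent random restarts.
#' @param max_iter Cap on Lloyd iterations per restart.
#' @param seed RNG seed; the fit is deterministic given `seed`.
#' @return An [fc_partition()] with attributes `objective` (within-cluster
#'   dissimilarity sum) and `objective_trace` (per-iteration objectives of
#'   the winning restart).
#' @export
kmeans_fit <- function(A, K, n_restarts = 10L, max_iter = 300L, seed = 1L) {
  n <- nrow(A)
  if (K > n) stop("kmeans_fit: K must be <= n")
  Y <- unclass(A)
  if (K == 1L) {
    z <- fc_partition(rep(1L, n), K = 1L)
    ctr <- colMeans(Y)
    attr(z, "objective") <- sum(1 - as.numeric(cor(t(Y), ctr)))
    return(z)
  }

  # n x K matrix of 1 - Pearson(row, centroid)
  dissim_to <- function(centroids) {
    r <- suppressWarnings(cor(t(Y), t(centroids)))
    r[is.na(r)] <- 0  # degenerate (constant) centroid: treat as uninformative
    1 - r
  }
  objective_of <- function(assign, centroids) {
    D <- dissim_to(centroids)
    sum(D[cbind(seq_len(n), assign)])
  }

  run_once <- function() {
    centroids <- Y[sample.int(n, K), , drop = FALSE]
    assign <- max.col(-dissim_to(centroids), ties.method = "first")
    trace <- objective_of(assign, centroids)
    for (it in seq_len(max_iter)) {
      new_centroids <- centroids
      for (k in seq_len(K)) {
        members <- which(assign == k)
        if (length(members) > 0L)
          new_centroids[k, ] <- colMeans(Y[members, , drop = FALSE])
      }
      D <- dissim_to(new_centroids)
      # reseed empty clusters at the worst-fitting point
      for (k in seq_len(K)) {
        if (!any(assign == k)) {
          far <- which.max(D[cbind(seq_len(n), assign)])
          new_centroids[k, ] <- Y[far, ]
          D <- dissim_to(new_centroids)
        }
      }
      new_assign <- max.col(-D, ties.method = "first")
      new_obj <- sum(D[cbind(seq_len(n), new_assign)])
      if (new_obj > trace[length(trace)] + 1e-12) break  # surrogate safeguard
      centroids <- new_centroids
      changed <- !all(new_assign == assign)
      assign <- new_assign
      trace <- c(trace, new_obj)
      if (!changed) break
    }
    list(assign = assign, objective = trace[length(trace)], trace = trace)
  }

  best <- with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(r) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  })
  z <- fc_partition(best$assign, K = K)
  attr(z, "objective") <- best$objective
  attr(z, "objective_trace") <- best$trace
  z
}
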