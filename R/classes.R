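#' Functional-connectivity matrix
#'
#' Light wrapper around a symmetric numeric matrix of pairwise temporal
#' correlations between regions of interest (ROIs), with unit diagonal. The
#' matrix is the dense weighted adjacency matrix on which all community
#' detection in this package operates; no thresholding is ever applied.
#'
#' @param weights Symmetric n x n numeric matrix with unit diagonal.
#' @param roi_names Optional character vector of length n.
#' @param check Validate invariants (symmetry, unit diagonal, n >= 2).
#' @return An object of class `fc_matrix` (a numeric matrix with attributes).
#' @export
fc_matrix <- function(weights, roi_names = NULL, check = TRUE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (check) {
    n <- nrow(weights)
    if (n < 2L || ncol(weights) != n)
      stop("fc_matrix: 'weights' must be a square matrix with n >= 2")
    if (anyNA(weights) || any(!is.finite(weights)))
      stop("fc_matrix: non-finite entries in 'weights'")
    if (max(abs(weights - t(weights))) > 1e-8)
      stop("fc_matrix: 'weights' is not symmetric")
    if (max(abs(diag(weights) - 1)) > 1e-8)
      stop("fc_matrix: diagonal must be 1")
    if (!is.null(roi_names) && length(roi_names) != n)
      stop("fc_matrix: 'roi_names' must have length n")
  }
  if (!is.null(roi_names)) dimnames(weights) <- list(roi_names, roi_names)
  class(weights) <- c("fc_matrix", "matrix")
  weights
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d ROIs, edge weights in [%.3f, %.3f]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' Community partition
#'
#' A length-n vector of integer community labels in `{1..K}` together with
#' the declared community count K. K may exceed the number of labels
#' actually used (a fitted solution can leave communities empty; see
#' [is_valid_solution()]).
#'
#' @param labels Integer vector of community labels in `{1..K}`.
#' @param K Declared community count; defaults to `max(labels)`.
#' @return An object of class `fc_partition` (an integer vector with a `K`
#'   attribute).
#' @export
fc_partition <- function(labels, K = max(labels)) {
  labels <- as.integer(labels)
  if (length(labels) < 1L || anyNA(labels))
    stop("fc_partition: labels must be non-empty integers")
  if (any(labels < 1L))
    stop("fc_partition: labels must be >= 1")
  K <- as.integer(K)
  if (K < max(labels))
    stop("fc_partition: K smaller than the largest label used")
  structure(labels, K = K, class = "fc_partition")
}

#' @export
print.fc_partition <- function(x, ...) {
  cat(sprintf("<fc_partition> n=%d, K=%d, sizes: %s\n", length(x),
              partition_k(x), paste(tabulate(unclass(x), partition_k(x)),
                                    collapse = "/")))
  invisible(x)
}

#' Declared community count of a partition
#' @param z An `fc_partition` or plain label vector.
#' @return Integer K.
#' @export
partition_k <- function(z) {
  K <- attr(z, "K")
  if (is.null(K)) max(as.integer(z)) else as.integer(K)
}

#' Block-level edge-weight parameters
#'
#' The K x K symmetric matrices of per-community-pair edge-weight means
#' (`mu`) and variances (`sigma2`) of the Gaussian weighted stochastic block
#' model: an edge between a vertex in community a and one in community b has
#' weight distributed Normal(mu[a,b], sigma2[a,b]).
#'
#' @param mu K x K symmetric numeric matrix of block means.
#' @param sigma2 K x K symmetric numeric matrix of positive block variances.
#' @return An object of class `block_params` (list with `mu`, `sigma2`, `K`).
#' @export
block_params <- function(mu, sigma2) {
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2)
  K <- nrow(mu)
  if (ncol(mu) != K || !all(dim(sigma2) == K))
    stop("block_params: 'mu' and 'sigma2' must be K x K")
  if (max(abs(mu - t(mu))) > 1e-10 || max(abs(sigma2 - t(sigma2))) > 1e-10)
    stop("block_params: matrices must be symmetric")
  if (any(sigma2 <= 0))
    stop("block_params: all variances must be > 0")
  structure(list(mu = mu, sigma2 = sigma2, K = K), class = "block_params")
}

#' @export
print.block_params <- function(x, ...) {
  cat(sprintf("<block_params> K=%d\nmu:\n", x$K))
  print(round(x$mu, 4))
  cat("sigma2:\n")
  print(round(x$sigma2, 4))
  invisible(x)
}
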