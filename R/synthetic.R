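#' Planted partition with fixed community sizes
#'
#' Builds the ground-truth community assignment used by the synthetic
#' connectome generator: community k receives exactly `sizes[k]` ROIs. By
#' default the assignment is contiguous (ROIs 1..sizes[1] get label 1, and
#' so on); all downstream methods are permutation-equivariant, so an
#' optional seeded shuffle of ROI order is provided for convenience only.
#'
#' @param sizes Vector of positive community sizes; `length(sizes)` is K.
#' @param shuffle Randomly permute ROI order (labels still have the exact
#'   requested counts).
#' @param seed RNG seed, used only when `shuffle = TRUE`.
#' @return An [fc_partition()] with `n = sum(sizes)`.
#' @examples
#' table(make_planted_partition(c(30, 15, 25, 20, 10)))
#' @export
make_planted_partition <- function(sizes, shuffle = FALSE, seed = 1L) {
  if (length(sizes) == 0L || anyNA(sizes) || any(sizes <= 0) ||
      any(sizes != round(sizes)))
    stop("make_planted_partition: 'sizes' must be positive integers")
  labels <- rep.int(seq_along(sizes), times = sizes)
  if (shuffle)
    labels <- with_seed(seed, sample(labels))
  fc_partition(labels, K = length(sizes))
}

#' Draw block-level means and variances for the generator
#'
#' Samples the K x K mean and variance matrices that define a synthetic
#' connectome. Within-community means (diagonal of `mu`) are drawn uniformly
#' from `within_mean_range`, between-community means from
#' `between_mean_range`, and per-block standard deviations from `sd_range`
#' (then squared into variances); all matrices are symmetric by
#' construction. The default ranges mimic the spread of within- and
#' between-system average connectivity seen in large adult resting-state
#' cohorts.
#'
#' @param K Number of communities.
#' @param within_mean_range Length-2 interval for diagonal means.
#' @param between_mean_range Length-2 interval for off-diagonal means.
#' @param sd_range Length-2 positive interval for block standard deviations.
#' @param seed RNG seed; identical seeds give identical parameters.
#' @return A [block_params()] object.
#' @export
make_block_params <- function(K,
                              within_mean_range = c(0.3, 0.6),
                              between_mean_range = c(-0.05, 0.2),
                              sd_range = c(0.05, 0.15),
                              seed = 1L) {
  check_interval <- function(r, name, positive = FALSE) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2])
      stop(sprintf("make_block_params: '%s' must be an ordered interval", name))
    if (positive && r[1] <= 0)
      stop(sprintf("make_block_params: '%s' must be positive", name))
  }
  if (K < 1L) stop("make_block_params: K must be >= 1")
  check_interval(within_mean_range, "within_mean_range")
  check_interval(between_mean_range, "between_mean_range")
  check_interval(sd_range, "sd_range", positive = TRUE)

  with_seed(seed, {
    mu <- matrix(0, K, K)
    diag(mu) <- runif(K, within_mean_range[1], within_mean_range[2])
    if (K > 1L) {
      off <- runif(K * (K - 1L) / 2L,
                   between_mean_range[1], between_mean_range[2])
      mu[upper.tri(mu)] <- off
      mu[lower.tri(mu)] <- t(mu)[lower.tri(mu)]
    }
    sdm <- matrix(0, K, K)
    sdm[upper.tri(sdm, diag = TRUE)] <-
      runif(K * (K + 1L) / 2L, sd_range[1], sd_range[2])
    sdm[lower.tri(sdm)] <- t(sdm)[lower.tri(sdm)]
    block_params(mu, sdm^2)
  })
}

#' Sample a synthetic functional-connectivity matrix
#'
#' Draws each pairwise edge weight `A[i, j]` (i < j) from
#' `Normal(mu[z_i, z_j], sigma2[z_i, z_j])`, symmetrizes, and sets the
#' diagonal to 1, emulating a correlation matrix over ROIs with planted
#' block structure. Because draws are Gaussian they can stray outside
#' `[-1, 1]`; set `clip = TRUE` to truncate them back into correlation
#' range (off by default so the generative model stays exactly Gaussian).
#'
#' @param partition An [fc_partition()] giving community membership.
#' @param params A [block_params()] with K at least the largest label.
#' @param seed RNG seed; identical seeds give bit-identical matrices.
#' @param clip Clip sampled weights to `[-1, 1]`.
#' @param roi_names Optional ROI identifiers.
#' @return An [fc_matrix()].
#' @examples
#' z <- make_planted_partition(c(30, 15, 25, 20, 10))
#' p <- make_block_params(5, seed = 1)
#' A <- sample_fc_matrix(z, p, seed = 1)
#' @export
sample_fc_matrix <- function(partition, params, seed = 1L, clip = FALSE,
                             roi_names = NULL) {
  z <- as.integer(partition)
  n <- length(z)
  if (max(z) > params$K)
    stop("sample_fc_matrix: partition uses a label beyond params$K")
  with_seed(seed, {
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    zi <- matrix(z, n, n)[ut]          # row label, per upper-tri cell
    zj <- t(matrix(z, n, n))[ut]       # column label
    idx <- cbind(zi, zj)
    w <- stats::rnorm(sum(ut), mean = params$mu[idx],
                      sd = sqrt(params$sigma2[idx]))
    if (clip) w <- pmin(1, pmax(-1, w))
    A[ut] <- w
    A <- A + t(A)
    diag(A) <- 1
    fc_matrix(A, roi_names = roi_names)
  })
}

#' One-call synthetic connectome in the benchmark configuration
#'
#' Convenience wrapper producing the standard benchmark instance: n = 100
#' ROIs in five planted communities of sizes 30/15/25/20/10 with block
#' parameters drawn from the default ranges. A "strong signal" preset
#' (within-mean 0.6, between-mean 0, sd 0.05) is available for recovery
#' tests where every method should identify the planted partition exactly.
#'
#' @param sizes Community sizes (default `c(30, 15, 25, 20, 10)`).
#' @param signal `"default"` (parameters drawn from the default ranges) or
#'   `"strong"` (well-separated fixed parameters).
#' @param seed RNG seed controlling both parameter draw and edge sampling.
#' @param ... Passed on to [make_block_params()] for `signal = "default"`.
#' @return List with elements `A` ([fc_matrix()]), `partition`, `params`.
#' @export
simulate_connectome <- function(sizes = c(30, 15, 25, 20, 10),
                                signal = c("default", "strong"),
                                seed = 1L, ...) {
  signal <- match.arg(signal)
  K <- length(sizes)
  z <- make_planted_partition(sizes)
  params <- if (signal == "strong") {
    mu <- matrix(0, K, K); diag(mu) <- 0.6
    block_params(mu, matrix(0.05^2, K, K))
  } else {
    make_block_params(K, seed = seed, ...)
  }
  A <- sample_fc_matrix(z, params, seed = seed + 1L)
  list(A = A, partition = z, params = params)
}
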