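#' Relabel a partition to best match a reference
#'
#' Applies the mismatch-minimizing label permutation found by
#' [hamming_distance()] so that `other`'s labels align with those of
#' `reference`. The Hamming distance to the reference never increases.
#'
#' @param reference,other Partitions of the same vertex set with the same
#'   declared K.
#' @return `other` relabeled (an [fc_partition()]).
#' @export
align_to_reference <- function(reference, other) {
  if (length(reference) != length(other))
    stop("align_to_reference: partitions differ in length")
  if (partition_k(reference) != partition_k(other))
    stop("align_to_reference: partitions differ in K")
  perm <- hamming_distance(reference, other)$permutation
  fc_partition(perm[as.integer(other)], K = partition_k(reference))
}

#' Consensus partition by alignment and majority vote
#'
#' Aligns every solution to a reference solution via optimal (Hungarian)
#' relabeling and assigns each ROI the label it receives most often across
#' the aligned solutions; ties go to the smaller label. The reference is
#' either given by index or chosen as the solution with the highest score
#' (the customary rules: maximum log-likelihood for weighted-SBM pools,
#' maximum silhouette for the other methods).
#'
#' @param solutions List of partitions, all with the same n and K.
#' @param reference_index Index of the reference solution (default 1), used
#'   when `scores` is `NULL`.
#' @param scores Optional numeric vector (one per solution); the reference
#'   is then the highest-scoring solution (ties toward the smaller index).
#' @return A `consensus_result`: `reference_index`, `aligned` (list of
#'   relabeled partitions), `consensus` ([fc_partition()]), `agreement`
#'   (per-ROI fraction of aligned solutions voting for the consensus
#'   label), `n_labels_used`, and `valid` (does the consensus use all K
#'   labels).
#' @export
consensus_partition <- function(solutions, reference_index = 1L,
                                scores = NULL) {
  if (length(solutions) < 1L)
    stop("consensus_partition: need at least one solution")
  n <- length(solutions[[1]])
  K <- partition_k(solutions[[1]])
  ok <- vapply(solutions, function(s)
    length(s) == n && partition_k(s) == K, logical(1))
  if (!all(ok))
    stop("consensus_partition: solutions disagree in n or K")
  if (!is.null(scores)) {
    if (length(scores) != length(solutions))
      stop("consensus_partition: one score per solution required")
    reference_index <- which.max(scores)
  }
  reference <- solutions[[reference_index]]
  aligned <- lapply(solutions, function(s) align_to_reference(reference, s))
  votes <- vapply(aligned, as.integer, integer(n))
  votes <- matrix(votes, nrow = n)
  counts <- t(apply(votes, 1L, tabulate, nbins = K))
  counts <- matrix(counts, nrow = n)
  cons <- max.col(counts, ties.method = "first")
  agreement <- counts[cbind(seq_len(n), cons)] / length(solutions)
  structure(list(
    reference_index = reference_index,
    aligned = aligned,
    consensus = fc_partition(cons, K = K),
    agreement = agreement,
    n_labels_used = length(unique(cons)),
    valid = length(unique(cons)) == K), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> n=%d, K=%d (%d labels used%s), mean agreement %.3f\n",
    length(x$consensus), partition_k(x$consensus), x$n_labels_used,
    if (x$valid) "" else " - fewer than K", mean(x$agreement)))
  invisible(x)
}
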