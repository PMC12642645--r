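#' Read a functional-connectivity matrix from delimited text
#'
#' Accepts a square numeric block in CSV/TSV, with an optional header row
#' and/or leading column of ROI names (detected automatically). Small
#' asymmetries (up to `sym_tol`) are symmetrized with a warning; larger
#' ones are an error naming the offending cell. An off-unit diagonal is
#' forced to 1 with a warning.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) tries comma then tab then
#'   whitespace.
#' @param sym_tol Largest tolerated asymmetry `|A_ij - A_ji|`.
#' @return An [fc_matrix()].
#' @export
read_fc_matrix <- function(path, sep = NULL, sym_tol = 1e-8) {
  if (!file.exists(path)) stop("read_fc_matrix: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl(",", first, fixed = TRUE)) ","
           else if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  toks <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks[toks != ""][-1])))
  df <- read.table(path, sep = sep, header = has_header,
                   stringsAsFactors = FALSE, check.names = FALSE)
  roi_names <- NULL
  if (!is.numeric(df[[1]])) {  # leading ROI-name column
    roi_names <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else if (has_header) {
    roi_names <- colnames(df)
  }
  M <- as.matrix(df)
  if (!is.numeric(M))
    stop("read_fc_matrix: non-numeric entries in matrix block")
  if (nrow(M) != ncol(M))
    stop(sprintf("read_fc_matrix: matrix is %d x %d, not square",
                 nrow(M), ncol(M)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("read_fc_matrix: missing value at row %d, column %d",
                 bad[1], bad[2]))
  }
  asym <- abs(M - t(M))
  if (max(asym) > sym_tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "read_fc_matrix: asymmetry %.3g at cell (%d, %d) exceeds tolerance",
      max(asym), bad[1], bad[2]))
  }
  if (max(asym) > 0) {
    warning("read_fc_matrix: symmetrizing small asymmetries")
    M <- (M + t(M)) / 2
  }
  if (max(abs(diag(M) - 1)) > 0) {
    if (max(abs(diag(M) - 1)) > sym_tol)
      warning("read_fc_matrix: forcing diagonal to 1")
    diag(M) <- 1
  }
  dimnames(M) <- NULL
  fc_matrix(M, roi_names = roi_names)
}

#' Write a functional-connectivity matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles bit-for-bit.
#'
#' @param A An [fc_matrix()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @export
write_fc_matrix <- function(A, path, sep = ",") {
  M <- unclass(A)
  rn <- rownames(M)
  lines <- apply(M, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  if (!is.null(rn)) {
    lines <- paste(rn, lines, sep = sep)
    lines <- c(paste(c("roi", rn), collapse = sep), lines)
  }
  writeLines(lines, path)
}

#' Read a partition from two-column delimited text
#'
#' Expects columns `roi_id, label` (header optional); rows may appear in
#' any ROI order.
#'
#' @param path File path.
#' @param K Declared community count (default: largest label present).
#' @return An [fc_partition()].
#' @export
read_partition <- function(path, K = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, "[,\t ]")[[1]])))
  df <- read.table(path, sep = ",", header = has_header)
  if (ncol(df) < 2L) stop("read_partition: expected two columns")
  ord <- order(df[[1]])
  labels <- as.integer(df[[2]][ord])
  fc_partition(labels, K = if (is.null(K)) max(labels) else K)
}

#' Write a partition as two-column delimited text
#'
#' @param z An [fc_partition()].
#' @param path Output file path.
#' @export
write_partition <- function(z, path) {
  writeLines(c("roi_id,label",
               paste(seq_along(z), as.integer(z), sep = ",")), path)
}

#' Serialize a fit or selection summary to JSON text
#'
#' @param x A `wsbm_fit`, `k_selection` or plain list.
#' @param path Output file path.
#' @export
write_fit_summary <- function(x, path) {
  if (inherits(x, "wsbm_fit")) {
    x <- list(K = x$K_input, seed = x$seed, loglik = x$loglik,
              converged = x$converged, n_iter = x$n_iter,
              lambda = x$lambda, labels = as.integer(map_labels(x)),
              mu = x$block_params$mu, sigma2 = x$block_params$sigma2)
  } else if (inherits(x, "k_selection")) {
    x <- list(k_grid = x$k_grid, chosen_k = x$chosen_k,
              fallback = x$fallback, pools = x$pools,
              n_discarded = x$n_discarded, diffs_ci = x$diffs_ci,
              n_runs = x$n_runs, n_boot = x$n_boot, alpha = x$alpha,
              seed = x$seed)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Full simulation study: generate, fit, select K, score, compare
#'
#' Runs the complete benchmark on one synthetic planted-block connectome:
#' selects K for the weighted SBM by bootstrap log-likelihood differences,
#' traces silhouette curves over the K grid for spectral clustering and
#' correlation K-means (best of `n_reps` seeded replications per K, the
#' customary selection rule for those methods), computes recovery NMI /
#' Hamming of each method's solution at the planted K against the ground
#' truth, pairwise cross-method agreement, and a consensus partition of
#' the valid weighted-SBM solutions at the chosen K.
#'
#' @param sizes Planted community sizes.
#' @param signal Generator preset, see [simulate_connectome()].
#' @param k_grid Candidate K grid.
#' @param n_runs Weighted-SBM restarts per K.
#' @param n_boot Bootstrap replicates per transition.
#' @param n_reps Seeded replications per K for the baseline silhouette
#'   curves.
#' @param alpha CI miscoverage.
#' @param seed Master seed; every stage seed derives from it.
#' @return A `simulation_report` list; see Details in the package vignette.
#' @export
run_simulation_study <- function(sizes = c(30, 15, 25, 20, 10),
                                 signal = "default", k_grid = 2:8,
                                 n_runs = 100L, n_boot = 500L,
                                 n_reps = 10L, alpha = 0.05, seed = 1L) {
  sim <- simulate_connectome(sizes = sizes, signal = signal, seed = seed)
  truth <- sim$partition
  K_true <- length(sizes)
  D <- correlation_dissimilarity(sim$A)

  sel <- select_k(sim$A, k_grid = k_grid, n_runs = n_runs, n_boot = n_boot,
                  alpha = alpha, seed = seed)

  sil_curve <- function(fitter) {
    vapply(k_grid, function(k) {
      best <- -Inf
      for (r in seq_len(n_reps)) {
        z <- fitter(k, seed + 500L * k + r)
        if (length(unique(as.integer(z))) >= 2L)
          best <- max(best, silhouette_index(D, z))
      }
      best
    }, numeric(1))
  }
  sil_spectral <- sil_curve(function(k, s) spectral_fit(sim$A, k, seed = s))
  sil_kmeans <- sil_curve(function(k, s) kmeans_fit(sim$A, k, seed = s))

  pool_true <- sel$ensembles[[as.character(K_true)]]
  z_wsbm <- if (!is.null(pool_true) && length(pool_true$fits) > 0L)
    map_labels(best_fit(pool_true)) else map_labels(vb_fit(sim$A, K_true,
                                                           seed = seed))
  pick_by_sil <- function(fitter) {
    zs <- lapply(seq_len(n_reps), function(r) fitter(seed + 900L + r))
    sil <- vapply(zs, function(z)
      if (length(unique(as.integer(z))) >= 2L) silhouette_index(D, z)
      else -Inf, numeric(1))
    zs[[which.max(sil)]]
  }
  z_spec <- pick_by_sil(function(s) spectral_fit(sim$A, K_true, seed = s))
  z_km <- pick_by_sil(function(s) kmeans_fit(sim$A, K_true, seed = s))

  sols <- list(wsbm = z_wsbm, spectral = z_spec, kmeans = z_km)
  recovery <- lapply(sols, function(z) list(
    nmi = nmi(truth, z), hamming = hamming_distance(truth, z)$distance))
  pairs <- utils::combn(names(sols), 2, simplify = FALSE)
  cross <- lapply(pairs, function(p) list(
    pair = paste(p, collapse = "-"),
    nmi = nmi(sols[[p[1]]], sols[[p[2]]]),
    hamming = hamming_distance(sols[[p[1]]], sols[[p[2]]])$distance))

  cons <- NULL
  pool_sel <- sel$ensembles[[as.character(sel$chosen_k)]]
  if (!is.null(pool_sel) && length(pool_sel$fits) > 0L) {
    cons <- consensus_partition(lapply(pool_sel$fits, map_labels),
                                scores = pool_sel$loglik)
  }

  structure(list(
    package_version = as.character(packageVersion("fccomm")),
    config = list(sizes = sizes, signal = signal, k_grid = k_grid,
                  n_runs = n_runs, n_boot = n_boot, n_reps = n_reps,
                  alpha = alpha, seed = seed),
    selection = sel,
    chosen_k = sel$chosen_k,
    n_discarded = sel$n_discarded,
    silhouette = data.frame(K = k_grid, spectral = sil_spectral,
                            kmeans = sil_kmeans),
    solutions = sols,
    recovery = recovery,
    cross_method = cross,
    consensus = cons), class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("<simulation_report>\n")
  cat(sprintf("  chosen K* (weighted SBM): %d\n", x$chosen_k))
  cat(sprintf("  silhouette peak: spectral K=%d, kmeans K=%d\n",
              x$silhouette$K[which.max(x$silhouette$spectral)],
              x$silhouette$K[which.max(x$silhouette$kmeans)]))
  for (m in names(x$recovery))
    cat(sprintf("  %s recovery: NMI=%.3f, Hamming=%.3f\n", m,
                x$recovery[[m]]$nmi, x$recovery[[m]]$hamming))
  invisible(x)
}
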