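#!/usr/bin/env Rscript
# Fit all three community-detection methods at the planted K = 5 on the
# default-signal and strong-signal benchmark instances, using each
# method's final-solution rule: maximum log-likelihood over the valid
# ensemble for the weighted SBM; highest silhouette over 10 seeded
# replications for spectral clustering and correlation K-means. Writes the
# fitted labels and a recovery/agreement table.

library(fccomm)

dir.create("results", showWarnings = FALSE)
truth <- read_partition(file.path("results", "data", "truth.csv"), K = 5)

fit_all <- function(A) {
  D <- correlation_dissimilarity(A)
  pick_by_sil <- function(fitter) {
    zs <- lapply(1:10, function(s) fitter(s))
    sil <- vapply(zs, function(z)
      if (length(unique(as.integer(z))) >= 2) silhouette_index(D, z)
      else -Inf, numeric(1))
    zs[[which.max(sil)]]
  }
  list(
    wsbm = map_labels(best_fit(fit_ensemble(A, 5, n_runs = 100,
                                            base_seed = 1))),
    spectral = pick_by_sil(function(s) spectral_fit(A, 5, seed = s)),
    kmeans = pick_by_sil(function(s) kmeans_fit(A, 5, seed = s)))
}

rows <- list()
for (signal in c("default", "strong")) {
  A <- read_fc_matrix(file.path("results", "data",
                                sprintf("fc_%s.csv", signal)))
  sols <- fit_all(A)
  for (m in names(sols)) {
    write_partition(sols[[m]],
                    file.path("results", sprintf("labels_%s_%s.csv",
                                                 m, signal)))
    rows[[length(rows) + 1L]] <- data.frame(
      signal = signal, comparison = paste0(m, " vs truth"),
      nmi = nmi(truth, sols[[m]]),
      hamming = hamming_distance(truth, sols[[m]])$distance)
  }
  for (p in utils::combn(names(sols), 2, simplify = FALSE)) {
    rows[[length(rows) + 1L]] <- data.frame(
      signal = signal, comparison = paste(p, collapse = " vs "),
      nmi = nmi(sols[[p[1]]], sols[[p[2]]]),
      hamming = hamming_distance(sols[[p[1]]], sols[[p[2]]])$distance)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path("results", "method_agreement.csv"),
          row.names = FALSE)

cat("Recovery and cross-method agreement (NMI / Hamming):\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nAt strong signal every method should reach NMI = 1;",
    "at the default signal the weighted SBM and K-means recover the",
    "planted partition while spectral clustering is the most",
    "instance-sensitive of the three.\n")
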