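#!/usr/bin/env Rscript
# Generate the benchmark connectomes: the standard planted-block instance
# (n = 100 ROIs, five communities of sizes 30/15/25/20/10, block means and
# variances drawn from the default ranges) and its strong-signal variant
# (within-mean 0.6, between 0, sd 0.05) used for exact-recovery checks.
# Writes the matrices, ground-truth partitions and generator parameters as
# delimited text under results/data/.

library(fccomm)

seed <- 1L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_connectome(seed = seed)
strong <- simulate_connectome(signal = "strong", seed = seed)

write_fc_matrix(sim$A, file.path(out, "fc_default.csv"))
write_fc_matrix(strong$A, file.path(out, "fc_strong.csv"))
write_partition(sim$partition, file.path(out, "truth.csv"))
write.table(sim$params$mu, file.path(out, "block_means.csv"), sep = ",",
            row.names = FALSE, col.names = FALSE)
write.table(sim$params$sigma2, file.path(out, "block_variances.csv"),
            sep = ",", row.names = FALSE, col.names = FALSE)

cat("Planted configuration: n =", length(sim$partition),
    "ROIs, community sizes", paste(tabulate(unclass(sim$partition), 5),
                                   collapse = "/"), "\n")
cat("Default-signal block means (diagonal):",
    paste(round(diag(sim$params$mu), 3), collapse = ", "), "\n")
cat("Wrote", length(list.files(out)), "files to", out, "\n")
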