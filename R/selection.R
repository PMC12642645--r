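#' Bootstrap confidence interval for a successive-K log-likelihood difference
#'
#' Each bootstrap replicate draws one log-likelihood with replacement from
#' the pool of valid K+1 fits and one from the pool of valid K fits and
#' records their difference; the percentile `(alpha/2, 1 - alpha/2)`
#' interval of the replicates is returned. An alternative mode resamples
#' whole pools and differences their means.
#'
#' @param pool_k,pool_k1 Numeric log-likelihood pools for K and K+1.
#' @param n_boot Number of bootstrap replicates.
#' @param alpha Two-sided miscoverage; the interval is `(1 - alpha)` level.
#' @param seed RNG seed; deterministic given `seed`.
#' @param mode Resampling unit per replicate: `"pairwise"` (difference of
#'   single draws, default), `"mean_diff"` (difference of resampled-pool
#'   means) or `"max_diff"` (difference of resampled-pool maxima — the
#'   per-model statistic is then the best value over restarts, with the
#'   bootstrap propagating restart-to-restart optimizer uncertainty).
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_diff_ci <- function(pool_k, pool_k1, n_boot = 2000L, alpha = 0.05,
                              seed = 1L,
                              mode = c("pairwise", "mean_diff", "max_diff")) {
  mode <- match.arg(mode)
  if (length(pool_k) == 0L || length(pool_k1) == 0L)
    stop("bootstrap_diff_ci: empty pool")
  if (n_boot < 1L || alpha <= 0 || alpha >= 1)
    stop("bootstrap_diff_ci: invalid n_boot/alpha")
  # resample via indices: sample(x, ...) on a length-1 numeric pool would
  # draw from 1:x instead of from the pool
  draw <- function(pool, m) pool[sample.int(length(pool), m, replace = TRUE)]
  reps <- with_seed(seed, {
    if (mode == "pairwise") {
      draw(pool_k1, n_boot) - draw(pool_k, n_boot)
    } else {
      stat <- if (mode == "mean_diff") mean else max
      vapply(seq_len(n_boot), function(b) {
        stat(draw(pool_k1, length(pool_k1))) -
          stat(draw(pool_k, length(pool_k)))
      }, numeric(1))
    }
  })
  unname(quantile(reps, c(alpha / 2, 1 - alpha / 2)))
}

#' Choose the number of communities by bootstrap log-likelihood differences
#'
#' For each K on the grid, fits a multi-restart ensemble of variational
#' weighted-SBM runs and pools a model-fit statistic of the valid
#' solutions (those using exactly K communities). For each consecutive
#' transition K -> K+1 a bootstrap confidence interval of the
#' log-likelihood difference is formed; the chosen K* is the smallest K
#' whose interval reaches 0 (adding a community no longer credibly
#' improves the model). Transitions where either pool is empty are
#' skipped; if no evaluable interval stops the scan, the grid maximum is
#' returned with a warning flag.
#'
#' The per-fit selection statistic is the evidence lower bound (ELBO) by
#' default: the successive-K comparison is a Bayes factor on marginal
#' likelihoods, which the ELBO approximates, and its exact
#' Kullback-Leibler parameter penalty is what lets the comparison flatten
#' at the true K (the plug-in likelihood always gains a little from
#' fitting noise with an extra community, so it never flattens; it remains
#' available via `statistic = "loglik"`). A transition stops the scan when
#' its CI lower bound is at or below 0 — the interval either brackets 0 or
#' lies entirely below it; an entirely negative interval means K+1 is
#' credibly worse, which is a fortiori a stopping signal.
#'
#' @param A An [fc_matrix()].
#' @param k_grid Ascending integer grid of candidate K (default 2:20).
#' @param n_runs Restarts per K (the reference budget is 1000).
#' @param n_boot Bootstrap replicates per transition (reference 2000).
#' @param alpha CI miscoverage (0.05 for 95% intervals).
#' @param seed Master seed; all restart and bootstrap seeds derive from it.
#' @param prior,max_iter,tol,method Passed to [vb_fit()].
#' @param ... Further arguments (e.g. `init`) passed to [vb_fit()].
#' @param mode Passed to [bootstrap_diff_ci()]; default `"max_diff"` (the
#'   model's evidence estimate is its best restart; bootstrapping pool
#'   maxima propagates restart-to-restart uncertainty of that estimate).
#' @param statistic Per-fit value pooled for the comparison: `"elbo"`
#'   (evidence lower bound at the fitted posterior, default),
#'   `"objective"` (the fit's own final objective) or `"loglik"` (plug-in
#'   likelihood at MAP labels).
#' @return A `k_selection` object: `k_grid`, `pools` (per-K valid-run
#'   selection statistics), `loglik_pools` (plug-in log-likelihoods),
#'   `ensembles` (the `wsbm_pool`s), `n_discarded`, `diffs_ci` (data frame
#'   with k, k_next, lower, upper, evaluable, contains_zero, stops),
#'   `chosen_k`, `fallback` flag, `n_runs`, `n_boot`, `alpha`, `seed`.
#' @export
select_k <- function(A, k_grid = 2:20, n_runs = 100L, n_boot = 2000L,
                     alpha = 0.05, seed = 1L, prior = wsbm_prior(),
                     max_iter = 200L, tol = 1e-6,
                     mode = c("max_diff", "pairwise", "mean_diff"),
                     method = c("vem", "vb"),
                     statistic = c("elbo", "objective", "loglik"), ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  k_grid <- as.integer(k_grid)
  if (length(k_grid) < 2L || is.unsorted(k_grid, strictly = TRUE))
    stop("select_k: k_grid must be strictly ascending with length >= 2")
  ensembles <- vector("list", length(k_grid))
  names(ensembles) <- as.character(k_grid)
  for (i in seq_along(k_grid)) {
    ensembles[[i]] <- fit_ensemble(
      A, k_grid[i], n_runs = n_runs, prior = prior, max_iter = max_iter,
      tol = tol, base_seed = seed + (i - 1L) * n_runs, method = method, ...)
  }
  loglik_pools <- lapply(ensembles, `[[`, "loglik")
  pools <- switch(statistic,
    loglik = loglik_pools,
    elbo = lapply(ensembles, function(e)
      vapply(e$fits, `[[`, numeric(1), "elbo")),
    objective = lapply(ensembles, function(e) vapply(
      e$fits, function(f) f$objective_trace[length(f$objective_trace)],
      numeric(1))))
  if (all(lengths(pools) == 0L))
    stop("select_k: no valid solutions for any K on the grid")

  nt <- length(k_grid) - 1L
  ci <- data.frame(k = k_grid[-length(k_grid)], k_next = k_grid[-1],
                   lower = NA_real_, upper = NA_real_,
                   evaluable = FALSE, contains_zero = NA, stops = NA)
  for (t in seq_len(nt)) {
    if (length(pools[[t]]) > 0L && length(pools[[t + 1L]]) > 0L) {
      b <- bootstrap_diff_ci(pools[[t]], pools[[t + 1L]], n_boot = n_boot,
                             alpha = alpha, seed = seed + 100000L + t,
                             mode = mode)
      ci$lower[t] <- b[1]; ci$upper[t] <- b[2]
      ci$evaluable[t] <- TRUE
      ci$contains_zero[t] <- b[1] <= 0 && b[2] >= 0
      ci$stops[t] <- b[1] <= 0
    }
  }
  hit <- which(ci$evaluable & ci$stops)
  fallback <- length(hit) == 0L
  chosen <- if (fallback) {
    warning("select_k: no successive-K interval reaches 0; ",
            "returning the grid maximum")
    k_grid[length(k_grid)]
  } else {
    ci$k[hit[1]]
  }
  structure(list(k_grid = k_grid, pools = pools,
                 loglik_pools = loglik_pools, ensembles = ensembles,
                 n_discarded = vapply(ensembles, `[[`, integer(1),
                                      "n_discarded"),
                 diffs_ci = ci, chosen_k = chosen, fallback = fallback,
                 statistic = statistic, mode = mode,
                 n_runs = as.integer(n_runs), n_boot = as.integer(n_boot),
                 alpha = alpha, seed = as.integer(seed)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> K grid %d..%d, chosen K* = %d%s\n",
              min(x$k_grid), max(x$k_grid), x$chosen_k,
              if (x$fallback) " (fallback: no interval reached 0)" else ""))
  print(x$diffs_ci, row.names = FALSE)
  invisible(x)
}

#' Best fit of an ensemble by plug-in log-likelihood
#'
#' @param pool A `wsbm_pool` (or plain list of `wsbm_fit`s) with at least
#'   one fit.
#' @return The fit with the largest `loglik`; ties broken toward the
#'   smallest seed.
#' @export
best_fit <- function(pool) {
  fits <- if (inherits(pool, "wsbm_pool")) pool$fits else pool
  if (length(fits) == 0L) stop("best_fit: empty pool")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  sds <- vapply(fits, `[[`, integer(1), "seed")
  top <- which(ll == max(ll))
  fits[[top[which.min(sds[top])]]]
}
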