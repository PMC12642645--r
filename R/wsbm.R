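#' Prior for the Gaussian weighted stochastic block model
#'
#' Each unique block pair (a <= b) carries a conjugate normal-inverse-gamma
#' prior on its edge-weight mean and variance:
#' `sigma2 ~ IG(alpha0, beta0)` and `mu | sigma2 ~ N(m0, sigma2 / kappa0)`.
#' This is the conjugate exponential family for the natural parameters
#' `eta_ab = (mu/sigma2, -1/sigma2, -mu^2/sigma2)`. Community labels carry a
#' flat prior `1/K`. The defaults are weakly informative: prior mean 0,
#' pseudo-count 1, inverse-gamma shape 2 and scale 0.1.
#'
#' @param m0 Prior mean of block means.
#' @param kappa0 Prior pseudo-count (precision scaling) on the mean; > 0.
#' @param alpha0 Inverse-gamma shape; > 1 so the variance has a posterior
#'   mean.
#' @param beta0 Inverse-gamma scale; > 0.
#' @return An object of class `wsbm_prior`.
#' @export
wsbm_prior <- function(m0 = 0, kappa0 = 1, alpha0 = 2, beta0 = 0.1) {
  if (kappa0 <= 0 || alpha0 <= 1 || beta0 <= 0)
    stop("wsbm_prior: need kappa0 > 0, alpha0 > 1, beta0 > 0")
  structure(list(m0 = m0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "wsbm_prior")
}

# k-means++-style soft initialization: K prototype ROIs chosen with
# probability proportional to squared correlation distance from earlier
# prototypes; responsibilities softmax(conc * cor(profile_i, profile_pk)).
# Assumes the caller fixed the RNG state.
init_kmeanspp <- function(Y, K, conc) {
  n <- nrow(Y)
  protos <- sample.int(n, 1L)
  if (K > 1L) for (k in 2:K) {
    r <- suppressWarnings(cor(t(Y), t(Y[protos, , drop = FALSE])))
    r[is.na(r)] <- 0
    d2 <- apply(1 - r, 1L, min)^2
    d2[protos] <- 0
    if (sum(d2) == 0) d2[-protos] <- 1  # duplicate rows: fall back to uniform
    protos <- c(protos, sample.int(n, 1L, prob = d2 / sum(d2)))
  }
  r <- suppressWarnings(cor(t(Y), t(Y[protos, , drop = FALSE])))
  r[is.na(r)] <- 0
  e <- exp(conc * (r - apply(r, 1L, max)))
  e / rowSums(e)
}

#' Gaussian block-model log-likelihood of an FC matrix
#'
#' Evaluates the dense weighted-SBM likelihood: the sum over unordered
#' vertex pairs i < j of the log normal density of `A[i, j]` under its block
#' pair's mean and variance. The unit diagonal is excluded (it carries no
#' randomness).
#'
#' @param A An [fc_matrix()].
#' @param z An [fc_partition()] (or plain label vector).
#' @param params A [block_params()].
#' @return The log-likelihood (scalar).
#' @export
gaussian_loglik <- function(A, z, params) {
  z <- as.integer(z)
  n <- nrow(A)
  if (length(z) != n)
    stop("gaussian_loglik: partition length must match nrow(A)")
  if (max(z) > params$K)
    stop("gaussian_loglik: label exceeds params$K")
  if (any(params$sigma2 <= 0))
    stop("gaussian_loglik: variances must be positive")
  ut <- upper.tri(A)
  zi <- matrix(z, n, n)[ut]
  zj <- t(matrix(z, n, n))[ut]
  idx <- cbind(zi, zj)
  sum(dnorm(A[ut], mean = params$mu[idx], sd = sqrt(params$sigma2[idx]),
            log = TRUE))
}

#' Joint log density of data, labels and block parameters
#'
#' The complete-data objective: [gaussian_loglik()] plus the flat label
#' prior contribution `n * log(1/K)` plus (optionally) the log prior density
#' of each unique block pair's (mean, variance) under the conjugate
#' normal-inverse-gamma prior, whose normalizing constant is available in
#' closed form.
#'
#' @inheritParams gaussian_loglik
#' @param prior A [wsbm_prior()].
#' @param include_param_prior If `FALSE`, drop the parameter-prior term and
#'   return `gaussian_loglik + n * log(1/K)`.
#' @return The joint log density (scalar).
#' @export
joint_log_density <- function(A, z, params, prior = wsbm_prior(),
                              include_param_prior = TRUE) {
  K <- params$K
  out <- gaussian_loglik(A, z, params) + length(as.integer(z)) * log(1 / K)
  if (include_param_prior) {
    ui <- which(upper.tri(params$mu, diag = TRUE))
    mu <- params$mu[ui]; s2 <- params$sigma2[ui]
    # log NIG(mu, s2 | m0, kappa0, alpha0, beta0)
    lp <- dnorm(mu, prior$m0, sqrt(s2 / prior$kappa0), log = TRUE) +
      prior$alpha0 * log(prior$beta0) - lgamma(prior$alpha0) -
      (prior$alpha0 + 1) * log(s2) - prior$beta0 / s2
    out <- out + sum(lp)
  }
  out
}

#' Fit the weighted SBM by mean-field variational inference
#'
#' Approximates the posterior over community labels and block parameters by
#' coordinate-ascent inference under the mean-field factorization
#' `q(z) q(eta)`, minimizing the KL divergence to the true posterior.
#' Responsibilities are updated sequentially node by node; block-pair
#' parameters are updated in closed form (conjugate normal-inverse-gamma)
#' from responsibility-weighted sufficient statistics. The variational
#' objective is recorded each iteration and is non-decreasing; iteration
#' stops when its relative change falls below `tol` or after `max_iter`
#' iterations.
#'
#' Each restart is initialized (under `seed`) by seeding K prototype ROIs
#' with a k-means++-style draw — successive prototypes picked with
#' probability proportional to their squared correlation distance from the
#' prototypes already chosen — and softly assigning every ROI by the
#' correlation of its connectivity profile with each prototype's
#' (`init = "kmeanspp"`, the default). This keeps restarts diverse (the
#' multi-restart pools of [select_k()] rely on that) while placing most
#' starts inside the basin of a well-separated planted structure; a plain
#' symmetric Dirichlet(1) draw per node is available as
#' `init = "dirichlet"` but rarely reaches the planted optimum even at
#' strong signal.
#'
#' Two flavors of the label update are available. The default,
#' `method = "vem"` (variational EM), scores edges with the MAP block
#' parameters; surplus communities then persist as ordinary local optima,
#' which the valid-solution bookkeeping of [select_k()] relies on to form
#' pools above the true K. `method = "vb"` uses full expected log densities
#' under the conjugate posterior factor; its extra `-1/(2 kappa)` and
#' digamma terms act as a per-edge complexity penalty that empties surplus
#' communities (a Bayesian Occam effect), which is statistically cleaner at
#' fixed K but starves the successive-K comparison of valid overfitted
#' solutions. Both are exact coordinate ascent on their objective.
#'
#' @param A An [fc_matrix()].
#' @param K Number of communities (1 <= K <= n).
#' @param prior A [wsbm_prior()].
#' @param max_iter Maximum coordinate-ascent iterations.
#' @param tol Relative objective change declaring convergence.
#' @param seed RNG seed for the initialization; fits are deterministic
#'   given `seed`.
#' @param method `"vem"` (plug-in MAP parameters in the label updates,
#'   default) or `"vb"` (full variational Bayes).
#' @param init Initialization scheme: `"kmeanspp"` (default) or
#'   `"dirichlet"`.
#' @param init_conc Sharpness of the soft prototype assignment under
#'   `init = "kmeanspp"`.
#' @return A `wsbm_fit` object: `responsibilities` (n x K), `lambda`
#'   (mean responsibilities), `block_params` (posterior means),
#'   `objective_trace` (variational objective per iteration), `elbo` (the
#'   full-VB evidence lower bound evaluated at the fitted posterior,
#'   whichever method produced it), `loglik` (plug-in [gaussian_loglik()]
#'   at MAP labels and posterior-mean parameters), `K_input`, `seed`,
#'   `converged`, `n_iter`.
#' @export
vb_fit <- function(A, K, prior = wsbm_prior(), max_iter = 200L,
                   tol = 1e-6, seed = 1L, method = c("vem", "vb"),
                   init = c("kmeanspp", "dirichlet"), init_conc = 4) {
  method <- match.arg(method)
  init <- match.arg(init)
  n <- nrow(A)
  if (K < 1L || K > n) stop("vb_fit: need 1 <= K <= n")
  if (max_iter < 1L || tol <= 0) stop("vb_fit: invalid max_iter/tol")
  if (anyNA(A) || any(!is.finite(A))) stop("vb_fit: non-finite entries in A")
  A0 <- unclass(A)
  diag(A0) <- 0  # diagonal carries no information; excluded from all sums

  R0 <- with_seed(seed, {
    if (init == "dirichlet") {
      g <- matrix(rexp(n * K), n, K)
      g / rowSums(g)
    } else {
      init_kmeanspp(unclass(A), K, init_conc)
    }
  })
  res <- vb_cavi(A0, R0, prior$m0, prior$kappa0, prior$alpha0, prior$beta0,
                 as.integer(max_iter), tol, method == "vem")
  bp <- block_params((res$mu + t(res$mu)) / 2,
                     (res$sigma2 + t(res$sigma2)) / 2)
  fit <- structure(list(
    responsibilities = res$responsibilities,
    lambda = colMeans(res$responsibilities),
    block_params = bp,
    posterior = list(m = res$post_m, kappa = res$post_kappa,
                     alpha = res$post_alpha, beta = res$post_beta),
    objective_trace = as.numeric(res$objective_trace),
    elbo = res$elbo,
    K_input = as.integer(K),
    method = method,
    seed = as.integer(seed),
    converged = res$converged,
    n_iter = res$n_iter), class = "wsbm_fit")
  fit$loglik <- gaussian_loglik(A, map_labels(fit), bp)
  fit
}

#' @export
print.wsbm_fit <- function(x, ...) {
  cat(sprintf(
    "<wsbm_fit> K=%d, loglik=%.3f, ELBO=%.3f after %d iterations (%s)\n",
    x$K_input, x$loglik, x$objective_trace[length(x$objective_trace)],
    x$n_iter, if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Maximum-posterior community labels of a fit
#'
#' Label of vertex i is the argmax of its responsibility row; ties are
#' broken toward the smaller community index for determinism.
#'
#' @param fit A `wsbm_fit`.
#' @return An [fc_partition()] with `K = fit$K_input`.
#' @export
map_labels <- function(fit) {
  fc_partition(max.col(fit$responsibilities, ties.method = "first"),
               K = fit$K_input)
}

#' Does a fitted assignment use exactly K communities?
#'
#' A fitted solution is "valid" for a requested K when the number of
#' distinct labels it actually uses equals K; variational fits can leave
#' communities empty, and only valid solutions enter the K-selection pools.
#'
#' @param labels An [fc_partition()] or plain label vector.
#' @param K Requested community count.
#' @return Logical scalar.
#' @export
is_valid_solution <- function(labels, K) {
  length(unique(as.integer(labels))) == as.integer(K)
}

#' Multi-restart ensemble of variational fits at fixed K
#'
#' Runs [vb_fit()] with seeds `base_seed, base_seed + 1, ...` and keeps only
#' fits whose MAP labels use exactly K communities ([is_valid_solution()]).
#' The number of discarded (invalid) runs is recorded; an empty pool is
#' returned as such, never an error, so that K-selection can skip
#' unevaluable K values.
#'
#' @inheritParams vb_fit
#' @param n_runs Number of restarts.
#' @param base_seed Seed of the first restart.
#' @param ... Further arguments (e.g. `init`) passed to [vb_fit()].
#' @return A `wsbm_pool` object: list of valid `wsbm_fit`s plus `loglik`
#'   vector, `K`, `n_runs`, `n_discarded`, `seeds` of the valid runs.
#' @export
fit_ensemble <- function(A, K, n_runs = 100L, prior = wsbm_prior(),
                         max_iter = 200L, tol = 1e-6, base_seed = 1L,
                         method = c("vem", "vb"), ...) {
  method <- match.arg(method)
  if (n_runs < 1L) stop("fit_ensemble: n_runs must be >= 1")
  fits <- vector("list", n_runs)
  keep <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    f <- vb_fit(A, K, prior = prior, max_iter = max_iter, tol = tol,
                seed = base_seed + r - 1L, method = method, ...)
    keep[r] <- is_valid_solution(map_labels(f), K)
    fits[[r]] <- f
  }
  valid <- fits[keep]
  structure(list(
    fits = valid,
    loglik = vapply(valid, function(f) f$loglik, numeric(1)),
    K = as.integer(K),
    n_runs = as.integer(n_runs),
    n_discarded = sum(!keep),
    seeds = vapply(valid, function(f) f$seed, integer(1))),
    class = "wsbm_pool")
}

#' @export
print.wsbm_pool <- function(x, ...) {
  cat(sprintf("<wsbm_pool> K=%d: %d valid of %d runs\n",
              x$K, length(x$fits), x$n_runs))
  invisible(x)
}
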