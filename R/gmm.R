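#' Construct a Gaussian-mixture latent prior
#'
#' The latent embedding's prior is a K-component mixture of diagonal
#' Gaussians; components play the role of cell clusters.
#'
#' @param log_pi Length-K log mixture weights (normalised internally).
#' @param mu K x D matrix of component means.
#' @param sigma K x D matrix of component scales (standard deviations);
#'   floored at `sigma_floor`.
#' @param sigma_floor Smallest admissible component scale.
#' @return An object of class `gmm_prior`.
#' @export
gmm_prior <- function(log_pi, mu, sigma, sigma_floor = 1e-4) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  K <- length(log_pi)
  stopifnot(nrow(mu) == K, identical(dim(mu), dim(sigma)))
  log_pi <- log_pi - log(sum(exp(log_pi - max(log_pi)))) - max(log_pi)
  sigma <- pmax(sigma, sigma_floor)
  structure(list(K = K, D = ncol(mu), log_pi = as.numeric(log_pi),
                 mu = mu, sigma = sigma),
            class = "gmm_prior")
}

#' @export
print.gmm_prior <- function(x, ...) {
  cat(sprintf("Gaussian mixture prior: K = %d components in %d dimensions\n",
              x$K, x$D))
  cat("weights:", paste(sprintf("%.3f", exp(x$log_pi)), collapse = " "), "\n")
  invisible(x)
}

# Per-component diagonal-Gaussian log density: returns n x K matrix.
gmm_component_loglik <- function(z, prior) {
  z <- as.matrix(z)
  n <- nrow(z)
  out <- matrix(0, n, prior$K)
  for (k in seq_len(prior$K)) {
    mu <- prior$mu[k, ]; sg <- prior$sigma[k, ]
    zc <- sweep(z, 2L, mu)
    out[, k] <- -0.5 * sum(log(2 * pi * sg^2)) -
      0.5 * rowSums(sweep(zc, 2L, sg, "/")^2)
  }
  out
}

#' Cluster responsibilities under a Gaussian-mixture prior
#'
#' Posterior probability that each cell's latent code was generated by each
#' mixture component: `resp[i, k]` is proportional to
#' `pi_k * N(z_i | mu_k, diag(sigma_k^2))`, normalised per cell in log space.
#'
#' @param z Cells x D matrix of latent codes.
#' @param prior A [gmm_prior()].
#' @return Cells x K matrix of responsibilities; rows sum to 1.
#' @export
cluster_posterior <- function(z, prior) {
  stopifnot(inherits(prior, "gmm_prior"))
  z <- as.matrix(z)
  if (ncol(z) != prior$D) stop("latent dimension mismatch with prior")
  lr <- gmm_component_loglik(z, prior) +
    rep(prior$log_pi, each = nrow(z))
  m <- apply(lr, 1L, max)
  e <- exp(lr - m)
  e / rowSums(e)
}

#' Fit the initial Gaussian-mixture prior on warm-up embeddings
#'
#' Diagonal-covariance EM, initialised from a seeded k-means partition.
#' Deterministic given the seed. A component that empties out is re-seeded at
#' a random data point (at most 5 retries).
#'
#' @param embeddings Cells x D matrix (warm-up latent means).
#' @param K Number of mixture components (expected cell clusters).
#' @param seed Integer seed controlling the k-means and retry draws.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sigma_floor Smallest admissible component scale.
#' @return A [gmm_prior()].
#' @export
init_gmm_prior <- function(embeddings, K, seed = 1L, max_iter = 200L,
                           tol = 1e-6, sigma_floor = 1e-4) {
  z <- as.matrix(embeddings)
  n <- nrow(z); D <- ncol(z)
  if (n < K) stop("need at least K cells to fit a K-component mixture")
  if (K == 1L) {
    mu <- matrix(colMeans(z), 1L)
    sg <- matrix(apply(z, 2L, stats::sd), 1L)
    if (n == 1L) sg[] <- 1
    return(gmm_prior(log_pi = 0, mu = mu, sigma = sg, sigma_floor = sigma_floor))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(z, centers = K, nstart = 5L, iter.max = 50L))
  pi_k <- pmax(tabulate(km$cluster, K) / n, 1e-10)
  mu <- km$centers
  sg <- matrix(0, K, D)
  for (k in seq_len(K)) {
    idx <- km$cluster == k
    sg[k, ] <- if (sum(idx) > 1L) apply(z[idx, , drop = FALSE], 2L, stats::sd) else 1
  }
  sg <- pmax(sg, sigma_floor)

  loglik_old <- -Inf
  retries <- 0L
  for (it in seq_len(max_iter)) {
    prior <- gmm_prior(log(pi_k), mu, sg, sigma_floor)
    ll <- gmm_component_loglik(z, prior) + rep(prior$log_pi, each = n)
    m <- apply(ll, 1L, max)
    lse <- m + log(rowSums(exp(ll - m)))
    resp <- exp(ll - lse)
    nk <- colSums(resp)
    empty <- which(nk < 1e-8)
    if (length(empty)) {
      retries <- retries + 1L
      if (retries > 5L) stop("EM failed: component stayed empty after 5 re-initialisations")
      for (k in empty) {
        mu[k, ] <- z[sample.int(n, 1L), ]
        sg[k, ] <- pmax(apply(z, 2L, stats::sd), sigma_floor)
        pi_k[k] <- 1 / K
      }
      pi_k <- pi_k / sum(pi_k)
      next
    }
    pi_k <- nk / n
    mu <- crossprod(resp, z) / nk
    for (k in seq_len(K)) {
      zc <- sweep(z, 2L, mu[k, ])
      sg[k, ] <- sqrt(colSums(resp[, k] * zc^2) / nk[k])
    }
    sg <- pmax(sg, sigma_floor)
    loglik <- sum(lse)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- loglik
  }
  gmm_prior(log(pi_k), mu, sg, sigma_floor)
}

#' Heuristic estimate of the number of cell clusters
#'
#' Counts eigenvalues of the cell-cell Pearson correlation matrix (computed
#' on the joint standardised features) exceeding the 95th percentile of a
#' permutation null. A coarse heuristic: prefer passing a known K.
#'
#' @param x Cells x features matrix (e.g. log1p RNA counts).
#' @param n_perm Number of column permutations for the null.
#' @param seed Integer seed.
#' @return Estimated cluster count (at least 1).
#' @export
estimate_k <- function(x, n_perm = 20L, seed = 1L) {
  x <- as.matrix(x)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  keep <- apply(x, 2L, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  # per-gene standardisation removes the shared mean-expression profile that
  # would otherwise dominate the leading eigenvalue in data and null alike
  x <- scale(x)
  cc <- stats::cor(t(x))
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    xp <- apply(x, 2L, sample)
    ccp <- stats::cor(t(xp))
    null_max[p] <- max(eigen(ccp, symmetric = TRUE, only.values = TRUE)$values)
  }
  thr <- stats::quantile(null_max, 0.95, names = FALSE)
  # K clusters span K - 1 contrast directions once the common profile is
  # removed, so the cluster count is the significant-component count plus one
  max(1L, sum(ev > thr) + 1L)
}
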