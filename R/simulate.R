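# Seeded generator of paired RNA/ATAC counts with known cluster structure,
# matching the generative assumptions of the model: cluster -> latent code
# -> softplus linear maps -> NB gene counts / zero-inflated Poisson peaks.

#' Simulation settings
#'
#' @param n_cells,n_genes,n_peaks Matrix dimensions.
#' @param K_true Number of ground-truth clusters.
#' @param latent_dim Dimension of the true latent code.
#' @param cluster_separation Euclidean distance between component means
#'   (0 collapses all clusters onto one Gaussian).
#' @param rna_dispersion Gamma shape of the Gamma-Poisson gene model; smaller
#'   values give stronger over-dispersion.
#' @param atac_dropout Structural-zero probability applied to peak counts.
#' @param depth_lognormal_sigma Log-normal sigma of the per-cell depth
#'   factor scaling gene means.
#' @param rna_mean_scale,atac_mean_scale Overall scale of gene means and peak
#'   rates.
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_cells = 500L, n_genes = 200L, n_peaks = 500L,
                     K_true = 4L, latent_dim = 10L, cluster_separation = 8,
                     rna_dispersion = 2, atac_dropout = 0.5,
                     depth_lognormal_sigma = 0.2, rna_mean_scale = 1,
                     atac_mean_scale = 1, seed = 1L) {
  stopifnot(n_cells >= K_true, K_true >= 1L, n_genes >= 1L, n_peaks >= 1L,
            latent_dim >= 1L, cluster_separation >= 0, rna_dispersion > 0,
            atac_dropout >= 0, atac_dropout < 1, depth_lognormal_sigma >= 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks), K_true = as.integer(K_true),
                 latent_dim = as.integer(latent_dim),
                 cluster_separation = cluster_separation,
                 rna_dispersion = rna_dispersion, atac_dropout = atac_dropout,
                 depth_lognormal_sigma = depth_lognormal_sigma,
                 rna_mean_scale = rna_mean_scale,
                 atac_mean_scale = atac_mean_scale, seed = as.integer(seed)),
            class = "sim_spec")
}

# K unit-norm directions scaled so that component means sit at mutual
# distance `sep`: random orthonormal-ish directions from a QR decomposition.
component_means <- function(K, D, sep) {
  if (K == 1L || sep == 0) return(matrix(0, K, D))
  raw <- matrix(stats::rnorm(D * K), D, K)
  q <- qr.Q(qr(raw))[, seq_len(K), drop = FALSE] # orthonormal columns
  # orthonormal columns are at mutual distance sqrt(2); rescale
  t(q) * (sep / sqrt(2))
}

#' Simulate a paired RNA + ATAC profile with known truth
#'
#' Each cell draws a cluster uniformly, a latent code
#' `z ~ N(mu_c, I)`, gene means as `softplus(z %*% W_rna) * depth * scale`
#' with a per-cell log-normal depth factor, RNA counts from the Gamma-Poisson
#' (negative binomial) with shape `rna_dispersion`, peak rates as
#' `softplus(z %*% W_atac) * scale`, and ATAC counts Poisson with structural
#' zeros at probability `atac_dropout`. The linear-map loadings are drawn
#' once from a standard normal under the simulation seed and returned with the
#' output so imputation can be scored against the true means.
#'
#' @param spec A [sim_spec()].
#' @return A list: `profile` (a [joint_profile()] with `labels` set),
#'   `true_labels`, `true_z`, `true_rna_means`, `true_atac_rates`,
#'   `component_means`, `loadings`.
#' @export
simulate_joint <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$n_cells; D <- spec$latent_dim
  mu_k <- component_means(spec$K_true, D, spec$cluster_separation)
  labels <- sample.int(spec$K_true, n, replace = TRUE)
  z <- mu_k[labels, , drop = FALSE] + matrix(stats::rnorm(n * D), n, D)

  W_rna <- matrix(stats::rnorm(D * spec$n_genes), D) / sqrt(D)
  W_atac <- matrix(stats::rnorm(D * spec$n_peaks), D) / sqrt(D)
  depth <- exp(stats::rnorm(n, 0, spec$depth_lognormal_sigma))

  rna_means <- softplus_mat(z %*% W_rna) * depth * spec$rna_mean_scale
  atac_rates <- softplus_mat(z %*% W_atac) * spec$atac_mean_scale

  # Gamma-Poisson: rate ~ Gamma(shape = r, scale = mean / r), count ~ Poisson
  r <- spec$rna_dispersion
  lam <- matrix(stats::rgamma(n * spec$n_genes, shape = r,
                              scale = as.vector(rna_means) / r),
                n, spec$n_genes)
  rna_counts <- matrix(stats::rpois(n * spec$n_genes, as.vector(lam)),
                       n, spec$n_genes)

  atac_counts <- matrix(stats::rpois(n * spec$n_peaks, as.vector(atac_rates)),
                        n, spec$n_peaks)
  if (spec$atac_dropout > 0) {
    drop <- matrix(stats::runif(n * spec$n_peaks) < spec$atac_dropout,
                   n, spec$n_peaks)
    atac_counts[drop] <- 0L
  }

  jp <- joint_profile(rna_counts, atac_counts,
                      cell_ids = sprintf("cell%05d", seq_len(n)),
                      gene_ids = sprintf("gene%05d", seq_len(spec$n_genes)),
                      peak_ids = sprintf("chr1:%d-%d",
                                         seq_len(spec$n_peaks) * 1000L,
                                         seq_len(spec$n_peaks) * 1000L + 500L),
                      labels = as.character(labels))
  list(profile = jp, true_labels = labels, true_z = z,
       true_rna_means = rna_means, true_atac_rates = atac_rates,
       component_means = mu_k, loadings = list(rna = W_rna, atac = W_atac))
}
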