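# Shared fixtures: tiny profiles built in code, plus brute-force oracles
# kept independent of the package implementation.

# A 3-cell toy pair of matrices used by the filtering examples:
# cell3 detects only 1 gene; gene g4 is nonzero in cell3 only (and in one
# other cell), so dropping cell3 leaves g4 detected in 1 cell.
toy_profile <- function() {
  rna <- rbind(c(5L, 2L, 1L, 0L),
               c(3L, 0L, 2L, 1L),
               c(4L, 0L, 0L, 1L))
  atac <- rbind(c(1L, 0L, 2L, 1L),
                c(0L, 1L, 1L, 1L),
                c(2L, 1L, 0L, 1L))
  joint_profile(rna, atac,
                cell_ids = c("c1", "c2", "c3"),
                gene_ids = c("g1", "g2", "g3", "g4"),
                peak_ids = c("p1", "p2", "p3", "p4"))
}

# Small simulated profile reused by model-level tests.
small_sim <- function(seed = 11L, n_cells = 120L) {
  simulate_joint(sim_spec(n_cells = n_cells, n_genes = 40L, n_peaks = 80L,
                          K_true = 3L, latent_dim = 4L,
                          cluster_separation = 8, seed = seed))
}

small_config <- function(K = 3L) {
  model_config(K = K, latent_dim = 4L, hidden_dim = 16L, shared_dim = 32L,
               n_heads = 2L, head_dim = 8L)
}

# Brute-force ARI by explicit pair counting over all n-choose-2 pairs.
pair_count_ari <- function(a, b) {
  n <- length(a)
  ss <- 0; sd_ <- 0; ds <- 0; dd <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) ss <- ss + 1
      else if (sa && !sb) sd_ <- sd_ + 1
      else if (!sa && sb) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  tot <- ss + sd_ + ds + dd
  expected <- (ss + sd_) * (ss + ds) / tot
  maxi <- ((ss + sd_) + (ss + ds)) / 2
  if (maxi == expected) return(0)
  (ss - expected) / (maxi - expected)
}

# Dense-density responsibility oracle: direct normalised Gaussian densities.
dense_resp_oracle <- function(z, log_pi, mu, sigma) {
  K <- length(log_pi)
  dens <- vapply(seq_len(K), function(k) {
    exp(log_pi[k]) * prod(stats::dnorm(z, mu[k, ], sigma[k, ]))
  }, numeric(1))
  dens / sum(dens)
}
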