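# Network definition and probability machinery of the joint RNA+ATAC VAE.
#
# The encoder has a mask-attention RNA channel and a multi-head
# self-attention ATAC channel feeding a shared trunk that emits the mean and
# log-variance of the diagonal-Gaussian posterior over the latent code z.
# The prior over z is a K-component Gaussian mixture; cluster
# responsibilities p(c|z) weight the decoders through a cluster-attention
# gate. The RNA decoder emits Gamma (shape, rate) parameters whose
# Poisson marginal is negative binomial; the ATAC decoder emits a
# zero-inflated Poisson rate and non-dropout probability.

#' Model configuration
#'
#' @param n_genes,n_peaks Input dimensions (set automatically by
#'   [train_duet()] when omitted).
#' @param K Number of mixture components (expected cell clusters).
#' @param latent_dim Latent dimension of the common embedding z.
#' @param hidden_dim Width of the channel hidden layers.
#' @param shared_dim Width of the shared layer joining the two channels.
#' @param n_heads,head_dim Self-attention heads and per-head width;
#'   `n_heads * head_dim` must equal `hidden_dim`.
#' @param eps_rate Floor added to positive rate/shape parameters.
#' @param eps_prob Clamp width keeping probabilities inside (0, 1).
#' @param sigma_floor Floor added to posterior and prior scales.
#' @param lambda_consistency Weight of the cycle-consistency KL.
#' @param lambda_raw Weight of the raw-data auxiliary-encoder KL terms.
#' @param zip_target_mode How continuous TF-IDF values become ZIP targets:
#'   `"round"` (default), `"floor"`, or `"raw"` (continuous Poisson density).
#' @param detach_imputed If `TRUE`, gradients do not flow through the
#'   imputations into the consistency loss (ablation switch).
#' @param trainable_prior If `TRUE` (default) the mixture-prior parameters
#'   keep training by gradient after their EM initialisation.
#' @param modality `"joint"`, `"rna"` or `"atac"`; single-modality variants
#'   route one channel only and drop the cross-modal consistency term of the
#'   absent modality.
#' @return A list of class `duet_config`.
#' @export
model_config <- function(n_genes = NULL, n_peaks = NULL, K = 1L,
                         latent_dim = 10L, hidden_dim = 128L,
                         shared_dim = 256L, n_heads = 8L, head_dim = 16L,
                         eps_rate = 1e-8, eps_prob = 1e-6, sigma_floor = 1e-4,
                         lambda_consistency = 1, lambda_raw = 1,
                         zip_target_mode = c("round", "floor", "raw"),
                         detach_imputed = FALSE, trainable_prior = TRUE,
                         modality = c("joint", "rna", "atac")) {
  zip_target_mode <- match.arg(zip_target_mode)
  modality <- match.arg(modality)
  if (n_heads * head_dim != hidden_dim) {
    stop("n_heads * head_dim must equal hidden_dim (the attention inner width)")
  }
  if (latent_dim < 2L) stop("latent_dim must be at least 2")
  structure(list(n_genes = n_genes, n_peaks = n_peaks, K = as.integer(K),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 shared_dim = as.integer(shared_dim),
                 n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
                 eps_rate = eps_rate, eps_prob = eps_prob,
                 sigma_floor = sigma_floor,
                 lambda_consistency = lambda_consistency,
                 lambda_raw = lambda_raw,
                 zip_target_mode = zip_target_mode,
                 detach_imputed = detach_imputed,
                 trainable_prior = trainable_prior, modality = modality),
            class = "duet_config")
}

# Xavier-uniform weight matrix.
xavier <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

zeros_row <- function(m) matrix(0, 1L, m)
ones_row <- function(m) matrix(1, 1L, m)

# Parameters of one attention block (Wq/Wk/Wv column-blocked per head).
init_mhsa <- function(hd, nh) {
  list(Wq = ad_param(xavier(hd, hd * nh)), Wk = ad_param(xavier(hd, hd * nh)),
       Wv = ad_param(xavier(hd, hd * nh)), Wo = ad_param(xavier(hd * nh, hd)))
}

# RNA-style branch: linear -> layernorm -> batchnorm -> relu, gated by a
# softmax mask computed from the first hidden layer.
init_rna_branch <- function(n_in, H) {
  list(W = ad_param(xavier(n_in, H)), b = ad_param(zeros_row(H)),
       mask_W = ad_param(xavier(H, H)), mask_b = ad_param(zeros_row(H)),
       ln_g = ad_param(ones_row(H)), ln_b = ad_param(zeros_row(H)),
       bn_g = ad_param(ones_row(H)), bn_b = ad_param(zeros_row(H)))
}

# ATAC-style branch: linear -> batchnorm -> relu -> self-attention with
# residual skip -> layernorm.
init_atac_branch <- function(n_in, H, nh, hd) {
  c(list(W = ad_param(xavier(n_in, H)), b = ad_param(zeros_row(H)),
         bn_g = ad_param(ones_row(H)), bn_b = ad_param(zeros_row(H)),
         ln_g = ad_param(ones_row(H)), ln_b = ad_param(zeros_row(H))),
    init_mhsa(hd, nh))
}

init_gauss_head <- function(n_in, H, D) {
  # small log-variance weights keep initial posterior scales near
  # exp(lv_b / 2) regardless of input magnitude
  list(t_W = ad_param(xavier(n_in, H)), t_b = ad_param(zeros_row(H)),
       mu_W = ad_param(xavier(H, D)), mu_b = ad_param(zeros_row(D)),
       lv_W = ad_param(xavier(H, D) * 0.1), lv_b = ad_param(matrix(-1, 1L, D)))
}

#' Initialise an untrained network
#'
#' Builds all parameter tensors (Xavier-uniform weights, zero biases) for the
#' configured architecture. Called by [train_duet()]; exposed for direct
#' inspection and for forward-pass tests.
#'
#' @param cfg A [model_config()] with `n_genes`/`n_peaks` set.
#' @param seed Integer seed for the weight draws.
#' @param data_mean_rna Per-gene mean counts (length `n_genes` or scalar);
#'   the RNA decoder's rate bias starts at the matching marginal so the
#'   initial NB mean equals the per-gene data mean.
#' @param data_mean_atac Per-peak mean of the nonzero ZIP targets (length
#'   `n_peaks` or scalar); the initial Poisson rate starts there.
#' @param data_detect_atac Per-peak nonzero fraction (length `n_peaks` or
#'   scalar); the initial non-dropout probability starts there.
#' @return A list of class `duet_model`.
#' @export
duet_model_init <- function(cfg, seed = 1L, data_mean_rna = 1,
                            data_mean_atac = 1, data_detect_atac = 0.5) {
  stopifnot(inherits(cfg, "duet_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  H <- cfg$hidden_dim; D <- cfg$latent_dim; K <- cfg$K
  G <- cfg$n_genes; P <- cfg$n_peaks
  use_rna <- cfg$modality != "atac"
  use_atac <- cfg$modality != "rna"
  p <- list()
  bn <- list()

  if (use_rna) {
    p$enc_rna <- init_rna_branch(G, H)
    bn$enc_rna <- bn_state(H)
    p$aux_rna <- c(init_rna_branch(G, H), init_gauss_head(H, H, D))
    bn$aux_rna <- bn_state(H)
  }
  if (use_atac) {
    p$enc_atac <- init_atac_branch(P, H, cfg$n_heads, cfg$head_dim)
    bn$enc_atac <- bn_state(H)
    p$aux_atac <- c(init_atac_branch(P, H, cfg$n_heads, cfg$head_dim),
                    init_gauss_head(H, H, D))
    bn$aux_atac <- bn_state(H)
  }
  cat_dim <- H * (use_rna + use_atac)
  p$trunk <- list(shared_W = ad_param(xavier(cat_dim, cfg$shared_dim)),
                  shared_b = ad_param(zeros_row(cfg$shared_dim)))
  p$head <- init_gauss_head(cfg$shared_dim, H, D)

  # inverse softplus / logit, so the output biases land at the data marginals
  inv_sp <- function(y) {
    y <- pmax(y, 1e-6)
    ifelse(y > 30, y, log(expm1(y)))
  }
  logit <- function(p) { p <- pmin(pmax(p, 1e-4), 1 - 1e-4); log(p / (1 - p)) }
  mean_rna <- rep_len(pmax(data_mean_rna, 1e-3), max(G, 1L))
  mean_atac <- rep_len(pmax(data_mean_atac, 1e-3), max(P, 1L))
  det_atac <- rep_len(data_detect_atac, max(P, 1L))
  if (use_rna) {
    p$dec_rna <- list(
      in_W = ad_param(xavier(D, H)), in_b = ad_param(zeros_row(H)),
      mask_W = ad_param(xavier(D, H)), mask_b = ad_param(zeros_row(H)),
      ln_g = ad_param(ones_row(H)), ln_b = ad_param(zeros_row(H)),
      bn_g = ad_param(ones_row(H)), bn_b = ad_param(zeros_row(H)),
      h_W = ad_param(xavier(H, H)), h_b = ad_param(zeros_row(H)),
      ca_W = ad_param(xavier(K, H)), ca_b = ad_param(zeros_row(H)),
      alpha_W = ad_param(xavier(H, G)),
      alpha_b = ad_param(matrix(inv_sp(1), 1L, G)),
      beta_W = ad_param(xavier(H, G)),
      beta_b = ad_param(matrix(inv_sp(1 / mean_rna), 1L, G)))
    bn$dec_rna <- bn_state(H)
  }
  if (use_atac) {
    p$dec_atac <- c(
      list(in_W = ad_param(xavier(D, H)), in_b = ad_param(zeros_row(H)),
           bn_g = ad_param(ones_row(H)), bn_b = ad_param(zeros_row(H)),
           ln_g = ad_param(ones_row(H)), ln_b = ad_param(zeros_row(H)),
           ca_W = ad_param(xavier(K, H)), ca_b = ad_param(zeros_row(H)),
           mu_W = ad_param(xavier(H, P)),
           mu_b = ad_param(matrix(inv_sp(mean_atac), 1L, P)),
           tau_W = ad_param(xavier(H, P)),
           tau_b = ad_param(matrix(logit(det_atac), 1L, P))),
      init_mhsa(cfg$head_dim, cfg$n_heads))
    bn$dec_atac <- bn_state(H)
  }

  model <- list(cfg = cfg, params = p, bn = bn, prior = NULL,
                prior_params = NULL)
  class(model) <- "duet_model"
  model
}

# Flat list of every trainable parameter node.
model_params <- function(model, include_prior = TRUE) {
  out <- list()
  for (grp in model$params) for (q in grp) out[[length(out) + 1L]] <- q
  if (include_prior && !is.null(model$prior_params) &&
      model$cfg$trainable_prior) {
    for (q in model$prior_params) out[[length(out) + 1L]] <- q
  }
  out
}

# --- prior plumbing ---------------------------------------------------------

# Standard-normal single-component prior used during warm-up.
warmup_prior <- function(D) gmm_prior(log_pi = 0, mu = matrix(0, 1L, D),
                                      sigma = matrix(1, 1L, D))

# Install a fitted gmm_prior as trainable parameter nodes
# (weights via softmax logits, scales via softplus).
set_model_prior <- function(model, prior) {
  stopifnot(inherits(prior, "gmm_prior"))
  inv_sp <- function(y) log(expm1(pmax(y, 1e-6)))
  model$prior <- prior
  model$prior_params <- list(
    u = ad_param(matrix(prior$log_pi, 1L)),
    mu = ad_param(prior$mu),
    s = ad_param(inv_sp(pmax(prior$sigma - model$cfg$sigma_floor, 1e-6))))
  model
}

# Current numeric prior (reads back the trainable nodes if present).
model_prior <- function(model) {
  if (is.null(model$prior_params)) {
    if (is.null(model$prior)) warmup_prior(model$cfg$latent_dim) else model$prior
  } else {
    u <- as.numeric(model$prior_params$u$value)
    gmm_prior(log_pi = u - max(u) - log(sum(exp(u - max(u)))),
              mu = model$prior_params$mu$value,
              sigma = softplus_mat(model$prior_params$s$value) + model$cfg$sigma_floor,
              sigma_floor = model$cfg$sigma_floor)
  }
}

# Prior as tape nodes: list(log_pi (1xK), mu (KxD), sigma (KxD)).
prior_nodes <- function(model) {
  if (is.null(model$prior_params)) {
    pr <- model_prior(model)
    list(log_pi = matrix(pr$log_pi, 1L), mu = pr$mu, sigma = pr$sigma,
         K = pr$K, fixed = TRUE)
  } else {
    pp <- model$prior_params
    pi_n <- ad_softmax_rows(pp$u)
    list(log_pi = ad_log(pi_n), mu = pp$mu,
         sigma = ad_add(ad_softplus(pp$s), model$cfg$sigma_floor),
         K = ncol(pp$u$value), fixed = FALSE)
  }
}

# n x K node (or matrix) of log pi_c + log N(z | mu_c, sigma_c) columns, and
# the responsibility softmax. z is a node; prior entries may be constants.
resp_nodes <- function(z, pn) {
  D <- ncol(val(z))
  cols <- vector("list", pn$K)
  for (k in seq_len(pn$K)) {
    mu_k <- if (pn$fixed) pn$mu[k, , drop = FALSE] else ad_row(pn$mu, k)
    sg_k <- if (pn$fixed) pn$sigma[k, , drop = FALSE] else ad_row(pn$sigma, k)
    lpi_k <- if (pn$fixed) pn$log_pi[1L, k] else NULL
    zc <- ad_div(ad_sub(z, mu_k), sg_k)
    ll <- ad_scale(ad_add(ad_rowsums(ad_square(zc)),
                          ad_scale(ad_rowsums(ad_log(if (pn$fixed) {
                            matrix(sg_k, 1L)
                          } else sg_k)), 2)), -0.5)
    ll <- ad_add(ll, -0.5 * D * log(2 * pi))
    cols[[k]] <- if (pn$fixed) ad_add(ll, lpi_k) else {
      # broadcast the k-th log weight (1x1 slice of the 1xK node)
      ad_add(ll, ad_row_col(pn$log_pi, k))
    }
  }
  lj <- cols[[1L]]
  if (pn$K > 1L) for (k in 2:pn$K) lj <- ad_cbind(lj, cols[[k]])
  list(log_joint = lj, resp = ad_softmax_rows(lj))
}

# 1x1 slice of a row-vector node.
ad_row_col <- function(a, j) {
  va <- val(a)
  ad_node(va[, j, drop = FALSE], backward = function(g) {
    z <- matrix(0, 1L, ncol(va))
    z[1L, j] <- g
    acc_grad(a, z)
  })
}

# --- channel forwards (tape) ------------------------------------------------

# Elementwise gating by a softmax attention vector. The product is rescaled
# by the gate width so a near-uniform gate leaves activations at unit scale
# (the constant is absorbable into the following linear layer; it only
# conditions the optimisation).
gate_apply <- function(h, gate) ad_scale(ad_mul(h, gate), ncol(val(gate)))

rna_branch_fwd <- function(pp, st, x, training) {
  h1 <- ad_linear(x, pp$W, pp$b)
  mask <- ad_softmax_rows(ad_linear(h1, pp$mask_W, pp$mask_b))
  a <- ad_relu(ad_batchnorm(ad_layernorm(h1, pp$ln_g, pp$ln_b),
                            pp$bn_g, pp$bn_b, st, training))
  gate_apply(a, mask)
}

atac_branch_fwd <- function(pp, st, y, training, nh, hd) {
  h <- ad_relu(ad_batchnorm(ad_linear(y, pp$W, pp$b), pp$bn_g, pp$bn_b,
                            st, training))
  att <- ad_mhsa(h, pp$Wq, pp$Wk, pp$Wv, pp$Wo, nh, hd)
  ad_layernorm(ad_add(h, att), pp$ln_g, pp$ln_b)
}

gauss_head_fwd <- function(pp, a, sigma_floor, eps) {
  t1 <- ad_relu(ad_linear(a, pp$t_W, pp$t_b))
  mu <- ad_linear(t1, pp$mu_W, pp$mu_b)
  # log-variance bounded to keep every KL term finite and Adam's second
  # moments unpoisoned by transient spikes
  lv <- ad_clamp(ad_linear(t1, pp$lv_W, pp$lv_b), -8, 8)
  sigma <- ad_add(ad_exp(ad_scale(lv, 0.5)), sigma_floor)
  z <- if (is.null(eps)) mu else ad_add(mu, ad_mul(sigma, eps))
  list(mu = mu, sigma = sigma, z = z, eps = eps)
}

# Joint (or single-channel) encoder forward on the tape. eps = NULL gives
# deterministic z = mu.
encode_fwd <- function(model, x, y, training, eps) {
  cfg <- model$cfg
  chans <- list()
  if (cfg$modality != "atac") {
    chans$rna <- rna_branch_fwd(model$params$enc_rna, model$bn$enc_rna, x, training)
  }
  if (cfg$modality != "rna") {
    chans$atac <- atac_branch_fwd(model$params$enc_atac, model$bn$enc_atac, y,
                                  training, cfg$n_heads, cfg$head_dim)
  }
  cat <- if (length(chans) == 2L) ad_cbind(chans$rna, chans$atac) else chans[[1L]]
  shared <- ad_relu(ad_linear(cat, model$params$trunk$shared_W,
                              model$params$trunk$shared_b))
  gauss_head_fwd(model$params$head, shared, cfg$sigma_floor, eps)
}

aux_encode_fwd <- function(pp, st, input, kind, training, cfg) {
  a <- if (kind == "rna") {
    rna_branch_fwd(pp, st, input, training)
  } else {
    atac_branch_fwd(pp, st, input, training, cfg$n_heads, cfg$head_dim)
  }
  gauss_head_fwd(pp, a, cfg$sigma_floor, eps = NULL)
}

decode_rna_fwd <- function(model, z, resp, training) {
  pp <- model$params$dec_rna; cfg <- model$cfg
  h <- ad_linear(z, pp$in_W, pp$in_b)
  h <- ad_batchnorm(ad_layernorm(h, pp$ln_g, pp$ln_b), pp$bn_g, pp$bn_b,
                    model$bn$dec_rna, training)
  mask <- ad_softmax_rows(ad_linear(z, pp$mask_W, pp$mask_b))
  h <- gate_apply(h, mask)
  last <- ad_relu(ad_linear(h, pp$h_W, pp$h_b))
  ca <- ad_softmax_rows(ad_linear(resp, pp$ca_W, pp$ca_b))
  last <- gate_apply(last, ca)
  list(alpha = ad_add(ad_softplus(ad_linear(last, pp$alpha_W, pp$alpha_b)),
                      cfg$eps_rate),
       beta = ad_add(ad_softplus(ad_linear(last, pp$beta_W, pp$beta_b)),
                     cfg$eps_rate),
       cluster_attention = ca)
}

decode_atac_fwd <- function(model, z, resp, training) {
  pp <- model$params$dec_atac; cfg <- model$cfg
  h <- ad_batchnorm(ad_linear(z, pp$in_W, pp$in_b), pp$bn_g, pp$bn_b,
                    model$bn$dec_atac, training)
  att <- ad_mhsa(h, pp$Wq, pp$Wk, pp$Wv, pp$Wo, cfg$n_heads, cfg$head_dim)
  a <- ad_layernorm(ad_add(h, att), pp$ln_g, pp$ln_b)
  ca <- ad_softmax_rows(ad_linear(resp, pp$ca_W, pp$ca_b))
  a <- gate_apply(a, ca)
  tau_raw <- ad_sigmoid(ad_linear(a, pp$tau_W, pp$tau_b))
  list(mu = ad_add(ad_softplus(ad_linear(a, pp$mu_W, pp$mu_b)), cfg$eps_rate),
       tau = ad_add(ad_scale(tau_raw, 1 - 2 * cfg$eps_prob), cfg$eps_prob),
       cluster_attention = ca)
}

# Closed-form KL between diagonal Gaussians q1 -> q2, per cell (n x 1 node).
gauss_kl_nodes <- function(mu1, sigma1, mu2, sigma2) {
  r <- ad_div(sigma1, sigma2)
  d <- ad_div(ad_sub(mu1, mu2), sigma2)
  ad_scale(ad_rowsums(ad_sub(ad_add(ad_square(r), ad_square(d)),
                             ad_add(ad_scale(ad_log(ad_square(r)), 1),
                                    1))), 0.5)
}

# Single-sample GMM-VAE KL estimate per cell: log q(z) - sum_c r_c (log pi_c
# + log N(z|mu_c, sigma_c)) + sum_c r_c log r_c, at the sampled z.
kl_prior_nodes <- function(post, rn) {
  D <- ncol(val(post$mu))
  eps <- if (is.null(post$eps)) matrix(0, nrow(val(post$mu)), D) else post$eps
  const <- matrix(0.5 * D * log(2 * pi) + 0.5 * rowSums(eps * eps), ncol = 1L)
  logq <- ad_sub(ad_scale(ad_rowsums(ad_log(post$sigma)), -1), const)
  cross <- ad_rowsums(ad_mul(rn$resp, rn$log_joint))
  # entropy with log-responsibilities in log space (underflow-safe)
  log_resp <- ad_sub(rn$log_joint, ad_logsumexp_rows(rn$log_joint))
  ent <- ad_rowsums(ad_mul(rn$resp, log_resp))
  ad_add(ad_sub(logq, cross), ent)
}

# --- ZIP target discretisation ---------------------------------------------

zip_target <- function(tfidf, mode) {
  switch(mode,
         round = round(tfidf),
         floor = floor(tfidf),
         raw = tfidf)
}

# --- public forward-pass wrappers (plain numeric in/out) --------------------

#' Encode cells into the latent posterior
#'
#' Runs the (joint or single-channel) encoder in eval mode and returns the
#' approximate posterior over the latent code plus cluster responsibilities.
#'
#' @param model A `duet_model` (e.g. `fit$model` from [train_duet()]).
#' @param x Cells x genes count matrix (RNA channel input), or `NULL` for
#'   ATAC-only models.
#' @param y Cells x peaks TF-IDF matrix (ATAC channel input), or `NULL` for
#'   RNA-only models.
#' @param sample If `TRUE`, draw the reparameterised sample
#'   `z = mu + sigma * eps`; otherwise `z = mu` (deterministic mode).
#' @return A `latent_posterior` list: `mu_z`, `sigma_z`, `z_sample`, `resp`.
#' @export
encode_joint <- function(model, x = NULL, y = NULL, sample = FALSE) {
  stopifnot(inherits(model, "duet_model"))
  x <- if (is.null(x)) NULL else as.matrix(x)
  y <- if (is.null(y)) NULL else as.matrix(y)
  n <- if (!is.null(x)) nrow(x) else nrow(y)
  cfg <- model$cfg
  if (cfg$modality != "atac" && (is.null(x) || ncol(x) != cfg$n_genes)) {
    stop("RNA input missing or gene dimension mismatch")
  }
  if (cfg$modality != "rna" && (is.null(y) || ncol(y) != cfg$n_peaks)) {
    stop("ATAC input missing or peak dimension mismatch")
  }
  eps <- if (sample) matrix(stats::rnorm(n * cfg$latent_dim), n) else NULL
  post <- encode_fwd(model, x, y, training = FALSE, eps = eps)
  z <- val(post$z)
  if (any(!is.finite(z))) stop("non-finite activations in encoder output")
  resp <- cluster_posterior(z, model_prior(model))
  structure(list(mu_z = val(post$mu), sigma_z = val(post$sigma),
                 z_sample = z, resp = resp),
            class = "latent_posterior")
}

#' Decode latent codes into RNA negative-binomial parameters
#'
#' @param model A `duet_model`.
#' @param z Cells x D latent matrix.
#' @param resp Cells x K cluster responsibilities (drives the
#'   cluster-attention gate); defaults to the current prior's posterior at z.
#' @return List with `alpha` (Gamma shape), `beta` (Gamma rate) and the
#'   `cluster_attention` gate, all cells x features / hidden matrices.
#' @export
decode_rna <- function(model, z, resp = NULL) {
  stopifnot(inherits(model, "duet_model"), model$cfg$modality != "atac")
  z <- as.matrix(z)
  if (is.null(resp)) {
    pr <- model_prior(model)
    resp <- if (pr$K == model$cfg$K) cluster_posterior(z, pr) else {
      matrix(1 / model$cfg$K, nrow(z), model$cfg$K)
    }
  }
  if (ncol(as.matrix(resp)) != model$cfg$K) {
    stop("resp must have K = ", model$cfg$K, " columns")
  }
  out <- decode_rna_fwd(model, z, as.matrix(resp), training = FALSE)
  list(alpha = val(out$alpha), beta = val(out$beta),
       cluster_attention = val(out$cluster_attention))
}

#' Decode latent codes into ATAC zero-inflated-Poisson parameters
#'
#' @inheritParams decode_rna
#' @return List with `mu` (Poisson rate), `tau` (non-dropout probability) and
#'   the `cluster_attention` gate.
#' @export
decode_atac <- function(model, z, resp = NULL) {
  stopifnot(inherits(model, "duet_model"), model$cfg$modality != "rna")
  z <- as.matrix(z)
  if (is.null(resp)) {
    pr <- model_prior(model)
    resp <- if (pr$K == model$cfg$K) cluster_posterior(z, pr) else {
      matrix(1 / model$cfg$K, nrow(z), model$cfg$K)
    }
  }
  if (ncol(as.matrix(resp)) != model$cfg$K) {
    stop("resp must have K = ", model$cfg$K, " columns")
  }
  out <- decode_atac_fwd(model, z, as.matrix(resp), training = FALSE)
  list(mu = val(out$mu), tau = val(out$tau),
       cluster_attention = val(out$cluster_attention))
}

#' Imputation as distribution means
#'
#' Imputed RNA is the Gamma mean `alpha / beta` (the mean of the NB
#' marginal); imputed ATAC is the Poisson rate `mu`.
#'
#' @param rna_out Output of [decode_rna()] (or `NULL`).
#' @param atac_out Output of [decode_atac()] (or `NULL`).
#' @return List with `imputed_rna` and `imputed_atac` (either may be `NULL`).
#' @export
impute_means <- function(rna_out = NULL, atac_out = NULL) {
  list(imputed_rna = if (!is.null(rna_out)) rna_out$alpha / rna_out$beta,
       imputed_atac = if (!is.null(atac_out)) atac_out$mu)
}

#' Evidence-lower-bound terms for one forward pass
#'
#' Computes the negative log-likelihood of both observation models and the
#' single-sample Monte-Carlo estimate of the latent-vs-mixture-prior KL. The
#' mixture-assignment KL of the generative identity vanishes because the
#' variational cluster posterior is defined to equal the generative one.
#'
#' @param x Cells x genes counts (RNA targets), or `NULL`.
#' @param y Cells x peaks ZIP targets (discretised TF-IDF), or `NULL`.
#' @param posterior A `latent_posterior` (from [encode_joint()]).
#' @param rna_out,atac_out Decoder outputs evaluated at `posterior$z_sample`.
#' @param prior A [gmm_prior()].
#' @return A `loss_report` list with per-batch sums (`nll_rna`, `nll_atac`,
#'   `kl_prior`, `kl_consistency = 0`, `total`) and per-cell means
#'   (`per_cell`).
#' @export
elbo_terms <- function(x, y, posterior, rna_out, atac_out, prior) {
  stopifnot(inherits(posterior, "latent_posterior"), inherits(prior, "gmm_prior"))
  n <- nrow(posterior$mu_z)
  nll_rna <- if (!is.null(x)) {
    -sum(nb_log_pmf(as.matrix(x), rna_out$alpha, rna_out$beta))
  } else 0
  nll_atac <- if (!is.null(y)) {
    y <- as.matrix(y)
    pos <- y > 0
    lp <- ifelse(pos,
                 log(atac_out$tau) + y * log(atac_out$mu) - atac_out$mu - lgamma(y + 1),
                 log((1 - atac_out$tau) + atac_out$tau * exp(-atac_out$mu)))
    -sum(lp)
  } else 0
  z <- posterior$z_sample
  eps_hat <- (z - posterior$mu_z) / posterior$sigma_z
  logq <- -rowSums(log(posterior$sigma_z)) - 0.5 * rowSums(eps_hat^2) -
    0.5 * ncol(z) * log(2 * pi)
  lj <- gmm_component_loglik(z, prior) + rep(prior$log_pi, each = n)
  resp <- posterior$resp
  kl <- sum(logq - rowSums(resp * lj) + rowSums(resp * log(pmax(resp, 1e-300))))
  total <- nll_rna + nll_atac + kl
  structure(list(nll_rna = nll_rna, nll_atac = nll_atac, kl_prior = kl,
                 kl_consistency = 0, total = total,
                 per_cell = c(nll_rna = nll_rna / n, nll_atac = nll_atac / n,
                              kl_prior = kl / n, total = total / n)),
            class = "loss_report")
}

#' Cycle-consistency loss between joint and imputed-single-modality posteriors
#'
#' Sum of the two closed-form diagonal-Gaussian KL divergences
#' `KL(q(z|x,y) || q(z|x_imputed)) + KL(q(z|x,y) || q(z|y_imputed))`,
#' averaged over cells. Either auxiliary posterior may be `NULL`
#' (single-modality models).
#'
#' @param posterior_raw Joint posterior on raw data (`latent_posterior`).
#' @param posterior_from_imputed_rna,posterior_from_imputed_atac Posteriors
#'   of the auxiliary encoders applied to the imputations.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(posterior_raw, posterior_from_imputed_rna = NULL,
                             posterior_from_imputed_atac = NULL) {
  kl12 <- function(p, q) {
    if (!identical(dim(p$mu_z), dim(q$mu_z))) stop("posterior shape mismatch")
    r2 <- (p$sigma_z / q$sigma_z)^2
    mean(0.5 * rowSums(r2 + ((p$mu_z - q$mu_z) / q$sigma_z)^2 - log(r2) - 1))
  }
  out <- 0
  if (!is.null(posterior_from_imputed_rna)) {
    out <- out + kl12(posterior_raw, posterior_from_imputed_rna)
  }
  if (!is.null(posterior_from_imputed_atac)) {
    out <- out + kl12(posterior_raw, posterior_from_imputed_atac)
  }
  out
}

# --- full training-step graph ----------------------------------------------

# Build the complete loss graph for one minibatch. Returns the scalar
# objective node (per-cell mean scale) plus the numeric term values.
# `cache` optionally carries precomputed lgamma tables for the batch.
duet_loss_graph <- function(model, xb, yb_tfidf, yb_target, training = TRUE,
                            eps = NULL, cache = NULL) {
  cfg <- model$cfg
  n <- if (!is.null(xb)) nrow(xb) else nrow(yb_tfidf)
  post <- encode_fwd(model, xb, yb_tfidf, training, eps)
  pn <- prior_nodes(model)
  rn <- resp_nodes(post$z, pn)
  kl_pr <- ad_sum(kl_prior_nodes(post, rn))

  # during warm-up the prior has a single component but the
  # cluster-attention gate is sized for the final K: feed it uniform weights
  resp_dec <- if (pn$K == cfg$K) rn$resp else matrix(1 / cfg$K, n, cfg$K)

  nll_r <- NULL; nll_a <- NULL
  rna_out <- NULL; atac_out <- NULL
  if (cfg$modality != "atac") {
    rna_out <- decode_rna_fwd(model, post$z, resp_dec, training)
    nll_r <- ad_nb_nll_sum(xb, rna_out$alpha, rna_out$beta,
                           lgamma_x1 = cache$lg_x1)
  }
  if (cfg$modality != "rna") {
    atac_out <- decode_atac_fwd(model, post$z, resp_dec, training)
    nll_a <- ad_zip_nll_sum(yb_target, atac_out$mu, atac_out$tau,
                            lgamma_y1 = cache$lg_y1)
  }

  # cycle consistency through the imputations
  kl_cons <- NULL
  kl_raw <- NULL
  add_kl <- function(acc, term) if (is.null(acc)) term else ad_add(acc, term)
  if (cfg$modality != "atac") {
    imp_rna <- ad_div(rna_out$alpha, rna_out$beta)
    if (cfg$detach_imputed) imp_rna <- val(imp_rna)
    aux_r <- aux_encode_fwd(model$params$aux_rna, model$bn$aux_rna, imp_rna,
                            "rna", training, cfg)
    kl_cons <- add_kl(kl_cons, ad_sum(gauss_kl_nodes(post$mu, post$sigma,
                                                     aux_r$mu, aux_r$sigma)))
    aux_r_raw <- aux_encode_fwd(model$params$aux_rna, model$bn$aux_rna, xb,
                                "rna", training, cfg)
    kl_raw <- add_kl(kl_raw, ad_sum(gauss_kl_nodes(post$mu, post$sigma,
                                                   aux_r_raw$mu, aux_r_raw$sigma)))
  }
  if (cfg$modality != "rna") {
    imp_atac <- atac_out$mu
    if (cfg$detach_imputed) imp_atac <- val(imp_atac)
    aux_a <- aux_encode_fwd(model$params$aux_atac, model$bn$aux_atac, imp_atac,
                            "atac", training, cfg)
    kl_cons <- add_kl(kl_cons, ad_sum(gauss_kl_nodes(post$mu, post$sigma,
                                                     aux_a$mu, aux_a$sigma)))
    aux_a_raw <- aux_encode_fwd(model$params$aux_atac, model$bn$aux_atac,
                                yb_tfidf, "atac", training, cfg)
    kl_raw <- add_kl(kl_raw, ad_sum(gauss_kl_nodes(post$mu, post$sigma,
                                                   aux_a_raw$mu, aux_a_raw$sigma)))
  }

  obj <- kl_pr
  if (!is.null(nll_r)) obj <- ad_add(obj, nll_r)
  if (!is.null(nll_a)) obj <- ad_add(obj, nll_a)
  if (cfg$lambda_consistency != 0) {
    obj <- ad_add(obj, ad_scale(kl_cons, cfg$lambda_consistency))
  }
  if (cfg$lambda_raw != 0) obj <- ad_add(obj, ad_scale(kl_raw, cfg$lambda_raw))
  obj <- ad_scale(obj, 1 / n)

  list(objective = obj,
       terms = c(nll_rna = if (is.null(nll_r)) 0 else val(nll_r)[1L],
                 nll_atac = if (is.null(nll_a)) 0 else val(nll_a)[1L],
                 kl_prior = val(kl_pr)[1L],
                 kl_consistency = if (is.null(kl_cons)) 0 else val(kl_cons)[1L],
                 kl_raw = if (is.null(kl_raw)) 0 else val(kl_raw)[1L]),
       n = n)
}

# --- checkpointing ----------------------------------------------------------

#' Save / load a trained model
#'
#' The checkpoint is a single RDS file holding every parameter array, the
#' batch-norm running statistics, the configuration and the mixture prior;
#' save then load round-trips bit-exactly.
#'
#' @param model A `duet_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the reconstructed `duet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "duet_model"))
  pv <- lapply(model$params, function(grp) lapply(grp, function(p) p$value))
  bnv <- lapply(model$bn, function(st) list(running_mean = st$running_mean,
                                            running_var = st$running_var))
  prv <- if (!is.null(model$prior_params)) {
    lapply(model$prior_params, function(p) p$value)
  }
  saveRDS(list(cfg = model$cfg, params = pv, bn = bnv, prior = model$prior,
               prior_params = prv), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- duet_model_init(ck$cfg, seed = 1L)
  for (g in names(ck$params)) {
    for (q in names(ck$params[[g]])) model$params[[g]][[q]]$value <- ck$params[[g]][[q]]
  }
  for (g in names(ck$bn)) {
    model$bn[[g]]$running_mean <- ck$bn[[g]]$running_mean
    model$bn[[g]]$running_var <- ck$bn[[g]]$running_var
  }
  model$prior <- ck$prior
  if (!is.null(ck$prior_params)) {
    model <- set_model_prior(model, ck$prior)
    for (q in names(ck$prior_params)) model$prior_params[[q]]$value <- ck$prior_params[[q]]
  }
  model
}
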