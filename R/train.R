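# Optimisation: Adam on the minibatch objective, with a standard-normal
# warm-up phase before the mixture prior is initialised by EM on the
# warm-up embeddings.

#' Training configuration
#'
#' Defaults follow the published schedule: Adam, minibatches of 128,
#' learning rate 5e-3, 30 epochs.
#'
#' @param batch_size Cells per minibatch.
#' @param learning_rate Adam step size.
#' @param max_epochs Total epochs (warm-up included).
#' @param warmup_epochs Epochs trained under a standard-normal prior before
#'   the Gaussian-mixture prior is fitted on the warm-up embeddings.
#' @param seed Integer seed governing shuffling, reparameterisation draws and
#'   weight initialisation.
#' @param grad_clip Global gradient-norm clip (a numerical safeguard;
#'   `Inf` disables it).
#' @param early_stop_patience Optional: stop when the per-cell total loss has
#'   not improved for this many consecutive epochs.
#' @param verbose Print one loss line per epoch.
#' @return A list of class `duet_train_config`.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 5e-3,
                         max_epochs = 30L, warmup_epochs = 5L, seed = 1L,
                         grad_clip = 50, early_stop_patience = NULL,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, warmup_epochs < max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 seed = as.integer(seed), grad_clip = grad_clip,
                 early_stop_patience = early_stop_patience,
                 verbose = isTRUE(verbose)),
            class = "duet_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = Inf) {
  state$t <- state$t + 1L
  if (is.finite(clip)) {
    sq <- 0
    for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    nrm <- sqrt(sq)
    if (nrm > clip) for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * (clip / nrm)
  }
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- params[[i]]$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]]$value <- params[[i]]$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

#' Fit the joint VAE to a paired profile
#'
#' Phase 1 (warm-up) trains under a standard-normal prior; the mixture prior
#' is then initialised by EM on the warm-up latent means and phase 2 trains
#' the full objective: NB + ZIP negative log-likelihoods, the
#' latent-vs-mixture KL, the cycle-consistency KL through the imputations,
#' and the raw-data auxiliary-encoder KL regulariser.
#'
#' @param jp A [joint_profile()]; it is TF-IDF transformed automatically if
#'   `atac_tfidf` is absent.
#' @param model_cfg A [model_config()] (dimensions are filled from `jp`).
#' @param train_cfg A [train_config()].
#' @return A `duet_fit` object: the trained `model`, the per-epoch loss table
#'   (`losses`, a tibble), the configuration, and the mixture prior.
#' @export
train_duet <- function(jp, model_cfg = model_config(),
                       train_cfg = train_config()) {
  stopifnot(inherits(jp, "joint_profile"), inherits(model_cfg, "duet_config"),
            inherits(train_cfg, "duet_train_config"))
  n <- length(jp$cell_ids)
  if (n == 0L) stop("empty data: no cells to train on")
  use_rna <- model_cfg$modality != "atac"
  use_atac <- model_cfg$modality != "rna"

  x <- if (use_rna) as.matrix(jp$rna_counts) else NULL
  ytf <- if (use_atac) {
    tf <- jp$atac_tfidf
    if (is.null(tf)) tf <- tfidf_transform(jp$atac_counts)
    as.matrix(tf)
  } else NULL
  ytarget <- if (use_atac) zip_target(ytf, model_cfg$zip_target_mode) else NULL

  model_cfg$n_genes <- if (use_rna) ncol(x) else NULL
  model_cfg$n_peaks <- if (use_atac) ncol(ytf) else NULL

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(train_cfg$seed)

  model <- duet_model_init(
    model_cfg, seed = train_cfg$seed,
    data_mean_rna = if (use_rna) colMeans(x) else 1,
    data_mean_atac = if (use_atac) {
      nz <- colSums(ytarget > 0)
      ifelse(nz > 0, colSums(ytarget) / pmax(nz, 1L), 1)
    } else 1,
    data_detect_atac = if (use_atac) colMeans(ytarget > 0) else 0.5)
  params <- model_params(model, include_prior = FALSE)
  opt <- adam_init(params)
  D <- model_cfg$latent_dim
  n_batches <- ceiling(n / train_cfg$batch_size)
  lg_x1_full <- if (use_rna) lgamma(x + 1) else NULL
  lg_y1_full <- if (use_atac) lgamma(ytarget + 1) else NULL

  loss_rows <- vector("list", train_cfg$max_epochs)
  best <- Inf; stale <- 0L

  for (epoch in seq_len(train_cfg$max_epochs)) {
    if (epoch == train_cfg$warmup_epochs + 1L) {
      # warm-up done: fit the mixture prior on current latent means
      emb <- encode_joint(model, x, ytf, sample = FALSE)$mu_z
      prior <- init_gmm_prior(emb, model_cfg$K, seed = train_cfg$seed,
                              sigma_floor = model_cfg$sigma_floor)
      model <- set_model_prior(model, prior)
      params <- model_params(model, include_prior = TRUE)
      opt <- adam_init(params)
    }
    ord <- sample.int(n)
    sums <- c(nll_rna = 0, nll_atac = 0, kl_prior = 0, kl_consistency = 0,
              kl_raw = 0)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * train_cfg$batch_size + 1L):min(b * train_cfg$batch_size, n)]
      xb <- if (use_rna) x[idx, , drop = FALSE] else NULL
      ytb <- if (use_atac) ytf[idx, , drop = FALSE] else NULL
      ytgb <- if (use_atac) ytarget[idx, , drop = FALSE] else NULL
      eps <- matrix(stats::rnorm(length(idx) * D), length(idx))
      ad_zero_grad(params)
      ad_tape_start()
      gr <- duet_loss_graph(model, xb, ytb, ytgb, training = length(idx) > 1L,
                            eps = eps,
                            cache = list(
                              lg_x1 = if (use_rna) lg_x1_full[idx, , drop = FALSE],
                              lg_y1 = if (use_atac) lg_y1_full[idx, , drop = FALSE]))
      if (!is.finite(val(gr$objective)[1L])) {
        ad_tape_stop()
        bad <- names(which(!is.finite(gr$terms)))
        stop(sprintf("non-finite loss at epoch %d, batch %d (term: %s)",
                     epoch, b, paste(bad, collapse = ", ")))
      }
      ad_backward(gr$objective)
      ad_tape_stop()
      opt <- adam_step(params, opt, train_cfg$learning_rate,
                       clip = train_cfg$grad_clip)
      sums <- sums + gr$terms
    }
    lam <- model_cfg$lambda_consistency
    total <- sums[["nll_rna"]] + sums[["nll_atac"]] + sums[["kl_prior"]] +
      lam * sums[["kl_consistency"]]
    loss_rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      phase = if (epoch <= train_cfg$warmup_epochs) "warmup" else "main",
      nll_rna = sums[["nll_rna"]], nll_atac = sums[["nll_atac"]],
      kl_prior = sums[["kl_prior"]],
      kl_consistency = sums[["kl_consistency"]], kl_raw = sums[["kl_raw"]],
      total = total, total_per_cell = total / n)
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d [%s] total/cell = %.4f", epoch,
                      loss_rows[[epoch]]$phase, total / n))
    }
    if (!is.null(train_cfg$early_stop_patience) &&
        epoch > train_cfg$warmup_epochs) {
      if (total < best - 1e-9) { best <- total; stale <- 0L } else stale <- stale + 1L
      if (stale >= train_cfg$early_stop_patience) {
        loss_rows <- loss_rows[seq_len(epoch)]
        break
      }
    }
  }

  losses <- dplyr::bind_rows(loss_rows)
  fit <- structure(list(model = model, losses = losses,
                        model_config = model_cfg, train_config = train_cfg,
                        prior = model_prior(model),
                        n_cells = n,
                        gene_ids = jp$gene_ids, peak_ids = jp$peak_ids,
                        cell_ids = jp$cell_ids),
                   class = "duet_fit")
  fit
}

#' @export
print.duet_fit <- function(x, ...) {
  cat(sprintf("duet_fit: %s model, %d cells, K = %d, D = %d\n",
              x$model_config$modality, x$n_cells, x$model_config$K,
              x$model_config$latent_dim))
  cat(sprintf("trained %d epochs; final total loss per cell: %.4f\n",
              nrow(x$losses), x$losses$total_per_cell[nrow(x$losses)]))
  invisible(x)
}

#' Convergence summary of a training run
#'
#' Reports the first epoch at which the relative change of the total loss
#' stayed below `tol` for three consecutive epochs.
#'
#' @param loss_table Per-epoch loss tibble (from `fit$losses`) with a `total`
#'   column, or a `duet_fit`.
#' @param tol Relative-change threshold.
#' @return A list with `converged` (logical) and `epoch` (integer or `NA`).
#' @export
convergence_report <- function(loss_table, tol = 1e-3) {
  if (inherits(loss_table, "duet_fit")) loss_table <- loss_table$losses
  tot <- loss_table$total
  if (length(tot) < 2L) stop("need at least 2 epochs to assess convergence")
  rel <- abs(diff(tot)) / pmax(abs(tot[-length(tot)]), 1e-12)
  ok <- rel < tol
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= 3L) {
      return(list(converged = TRUE, epoch = i + 1L))
    }
  }
  list(converged = FALSE, epoch = NA_integer_)
}
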