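# broom-style accessors and ggplot2 methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch loss table of a fit
#'
#' One row per epoch and loss term (long format), ready for plotting.
#'
#' @param x A `duet_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `phase`, `term`, `value`.
#' @export
tidy.duet_fit <- function(x, ...) {
  losses <- x$losses
  terms <- c("nll_rna", "nll_atac", "kl_prior", "kl_consistency", "kl_raw",
             "total")
  out <- lapply(terms, function(tm) {
    tibble::tibble(epoch = losses$epoch, phase = losses$phase, term = tm,
                   value = losses[[tm]])
  })
  dplyr::bind_rows(out)
}

#' One-row summary of a fit
#'
#' @param x A `duet_fit`.
#' @param ... Unused.
#' @return A tibble with the run's headline numbers.
#' @export
glance.duet_fit <- function(x, ...) {
  cv <- convergence_report(x$losses)
  last <- x$losses[nrow(x$losses), ]
  tibble::tibble(n_cells = x$n_cells,
                 n_genes = length(x$gene_ids),
                 n_peaks = length(x$peak_ids),
                 modality = x$model_config$modality,
                 k = x$model_config$K,
                 latent_dim = x$model_config$latent_dim,
                 epochs = nrow(x$losses),
                 converged = cv$converged,
                 convergence_epoch = cv$epoch,
                 final_total_per_cell = last$total_per_cell)
}

#' Per-cell tidy view of a clustering result
#'
#' @param x A `clustering_result`.
#' @param ... Unused.
#' @return A tibble with columns `cell` and `cluster`.
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$assignments), cluster = x$assignments)
}

#' @export
glance.clustering_result <- function(x, ...) {
  tibble::tibble(k_used = x$k_used, inertia = x$inertia,
                 ari_vs_reference = x$ari_vs_reference)
}

#' Training-curve plot
#'
#' Per-cell loss terms across epochs, faceted by term; the vertical line
#' marks the end of the warm-up phase.
#'
#' @param object A `duet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.duet_fit <- function(object, ...) {
  d <- tidy(object)
  d$value <- d$value / object$n_cells
  warm_end <- sum(object$losses$phase == "warmup")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss per cell") +
    ggplot2::theme_bw()
  if (warm_end > 0) {
    p <- p + ggplot2::geom_vline(xintercept = warm_end + 0.5, linetype = 2)
  }
  p
}

#' Embedding scatter plot
#'
#' First two latent dimensions of an embedding, optionally coloured by
#' labels.
#'
#' @param embedding Cells x D matrix (e.g. `encode_joint(...)$mu_z`).
#' @param labels Optional per-cell labels for colouring.
#' @param dims Which two latent dimensions to draw.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels = NULL, dims = c(1L, 2L)) {
  embedding <- as.matrix(embedding)
  d <- tibble::tibble(z1 = embedding[, dims[1L]], z2 = embedding[, dims[2L]])
  if (!is.null(labels)) d$label <- as.factor(labels)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z1, y = .data$z2)) +
    ggplot2::labs(x = paste0("z_", dims[1L]), y = paste0("z_", dims[2L])) +
    ggplot2::theme_bw()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.6)
}

#' @importFrom rlang .data
NULL
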