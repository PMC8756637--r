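# Downstream evaluation: k-means clustering of embeddings, adjusted Rand
# index, imputation accuracy metrics, and the end-to-end pipeline.

# k-means++ seeding: first centre uniform, then points sampled with
# probability proportional to squared distance from the nearest centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  # degenerate data (fewer than k distinct points) yields duplicate
  # centres; jitter them so Lloyd's algorithm can still run
  dup <- duplicated(centers)
  if (any(dup)) {
    sc <- max(stats::sd(x), 1e-8)
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), sd = 1e-6 * sc), sum(dup))
  }
  centers
}

#' K-means clustering of an embedding
#'
#' Lloyd's algorithm from k-means++ seedings, 10 restarts, keeping the
#' solution with the lowest within-cluster sum of squares. Deterministic
#' given the seed. Assignment ties break toward the lowest cluster index
#' (the behaviour of the underlying distance argmin).
#'
#' @param embedding Cells x D numeric matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param reference Optional reference labels; if given, the adjusted Rand
#'   index against them is filled in.
#' @param n_restarts Number of k-means++ restarts.
#' @return A `clustering_result` list: `assignments` (0-based integer IDs),
#'   `k_used`, `inertia`, `centers`, `ari_vs_reference` (or `NA`).
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L, reference = NULL,
                           n_restarts = 10L) {
  x <- as.matrix(embedding)
  if (k < 1L) stop("k must be at least 1")
  if (nrow(x) < k) stop("need at least k cells")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  last_err <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- kmeanspp_centers(x, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = cen, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) { last_err <<- e; NULL })
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed in every restart: ",
                          conditionMessage(last_err))
  ari <- if (!is.null(reference)) {
    adjusted_rand_index(best$cluster, reference)
  } else NA_real_
  structure(list(assignments = as.integer(best$cluster) - 1L,
                 k_used = as.integer(k), inertia = best$tot.withinss,
                 centers = best$centers, ari_vs_reference = ari),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d cells in %d clusters, inertia %.3f",
              length(x$assignments), x$k_used, x$inertia))
  if (!is.na(x$ari_vs_reference)) cat(sprintf(", ARI %.3f", x$ari_vs_reference))
  cat("\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions computed from the exact
#' contingency table: `(Index - Expected) / (Max - Expected)` under the
#' permutation model. Equals 1 for identical partitions and is ~0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length (any comparable type).
#' @return A real number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Imputation accuracy against known truth
#'
#' Per-cell Pearson correlation between the imputed profile and the true
#' mean profile, compared with the same correlation for the raw input; plus
#' mean squared error on a held-out entry mask.
#'
#' @param imputed Cells x features imputed matrix.
#' @param truth Cells x features true mean matrix.
#' @param raw Optional raw input matrix (baseline correlations).
#' @param mask Optional logical matrix (or 2-column index matrix) of held-out
#'   entries for the MSE.
#' @return A tibble with one row per cell: `cell`, `cor_imputed`,
#'   `cor_raw`, `imputed_wins`; the masked MSEs are attached as attributes
#'   `mse_imputed` / `mse_raw`.
#' @export
imputation_metrics <- function(imputed, truth, raw = NULL, mask = NULL) {
  imputed <- as.matrix(imputed); truth <- as.matrix(truth)
  if (!identical(dim(imputed), dim(truth))) stop("shape mismatch")
  row_cor <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      ti <- truth[i, ]; mi <- m[i, ]
      if (stats::sd(ti) == 0 || stats::sd(mi) == 0) return(NA_real_)
      stats::cor(mi, ti)
    }, numeric(1))
  }
  ci <- row_cor(imputed)
  cr <- if (!is.null(raw)) row_cor(as.matrix(raw)) else rep(NA_real_, nrow(truth))
  out <- tibble::tibble(cell = seq_len(nrow(truth)), cor_imputed = ci,
                        cor_raw = cr,
                        imputed_wins = !is.na(ci) & !is.na(cr) & ci > cr)
  if (!is.null(mask)) {
    attr(out, "mse_imputed") <- mean((imputed[mask] - truth[mask])^2)
    if (!is.null(raw)) {
      attr(out, "mse_raw") <- mean((as.matrix(raw)[mask] - truth[mask])^2)
    }
  }
  out
}

#' Impute both modalities of a profile with a trained model
#'
#' Encodes the cells (deterministic mode), decodes both channels and returns
#' the distribution means.
#'
#' @param fit A `duet_fit`.
#' @param jp A [joint_profile()] with matching feature spaces.
#' @return List with `posterior`, `imputed_rna`, `imputed_atac` (the ZIP
#'   Poisson mean, on the TF-IDF scale), `atac_tau` (non-dropout
#'   probabilities) and `imputed_accessibility` (the expected accessibility
#'   signal `tau * mu` mapped back through the IDF weights via
#'   [tfidf_inverse()]; use this for rate-scale comparisons).
#' @export
impute_profiles <- function(fit, jp) {
  stopifnot(inherits(fit, "duet_fit"), inherits(jp, "joint_profile"))
  cfg <- fit$model_config
  x <- if (cfg$modality != "atac") as.matrix(jp$rna_counts) else NULL
  ytf <- if (cfg$modality != "rna") {
    tf <- jp$atac_tfidf
    if (is.null(tf)) tf <- tfidf_transform(jp$atac_counts)
    as.matrix(tf)
  } else NULL
  post <- encode_joint(fit$model, x, ytf, sample = FALSE)
  rna_out <- if (cfg$modality != "atac") decode_rna(fit$model, post$z_sample, post$resp)
  atac_out <- if (cfg$modality != "rna") decode_atac(fit$model, post$z_sample, post$resp)
  imp <- impute_means(rna_out, atac_out)
  list(posterior = post, imputed_rna = imp$imputed_rna,
       imputed_atac = imp$imputed_atac,
       atac_tau = if (!is.null(atac_out)) atac_out$tau,
       imputed_accessibility = if (!is.null(atac_out)) {
         tfidf_inverse(atac_out$tau * atac_out$mu, jp$atac_counts)
       })
}

#' Run the full analysis pipeline
#'
#' read (or simulate) -> filter -> TF-IDF -> train -> encode -> impute ->
#' cluster -> score, writing every artifact plus a machine-readable manifest.
#'
#' @param config A list (or path to a YAML-like `key=value`/`key: value`
#'   file) with entries: either `rna_path` + `atac_path` or `sim` (a
#'   [sim_spec()]); `k` (cluster count; required unless labels exist);
#'   optional `filter` ([filter_spec()]), `model` (arguments to
#'   [model_config()]), `train` (arguments to [train_config()]), `seed`,
#'   `out_dir`.
#' @return Invisibly, a list with `fit`, `clustering`, `metrics`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_file(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  out_dir <- if (!is.null(config$out_dir)) config$out_dir else stop("config$out_dir is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  jp <- stage("read", {
    if (!is.null(config$sim)) {
      sp <- if (inherits(config$sim, "sim_spec")) config$sim else do.call(sim_spec, config$sim)
      sim <- simulate_joint(sp)
      truth <- sim
      sim$profile
    } else {
      read_joint_profile(config$rna_path, config$atac_path)
    }
  })
  fs <- if (!is.null(config$filter)) {
    if (inherits(config$filter, "filter_spec")) config$filter else do.call(filter_spec, config$filter)
  } else filter_spec(min_features_per_cell = 1L, min_cells_per_feature = 1L)
  jp <- stage("filter", filter_joint_profile(jp, fs))
  jp$atac_tfidf <- stage("tfidf", tfidf_transform(jp$atac_counts))

  k <- config$k
  if (is.null(k)) {
    if (!is.null(jp$labels)) {
      k <- length(unique(jp$labels))
    } else if (isTRUE(config$estimate_k)) {
      k <- stage("estimate_k", estimate_k(log1p(as.matrix(jp$rna_counts)), seed = seed))
    } else {
      stop("config$k is required when no labels are present and estimate_k is not set")
    }
  }

  margs <- if (!is.null(config$model)) config$model else list()
  margs$K <- as.integer(k)
  mcfg <- do.call(model_config, margs)
  targs <- if (!is.null(config$train)) config$train else list()
  if (is.null(targs$seed)) targs$seed <- seed
  tcfg <- do.call(train_config, targs)

  fit <- stage("train", train_duet(jp, mcfg, tcfg))
  imp <- stage("impute", impute_profiles(fit, jp))
  embedding <- imp$posterior$mu_z
  cl <- stage("cluster", kmeans_cluster(embedding, k = k, seed = seed,
                                        reference = jp$labels))
  metrics <- list(ari = cl$ari_vs_reference,
                  final_loss_per_cell = fit$losses$total_per_cell[nrow(fit$losses)],
                  convergence = convergence_report(fit$losses))
  if (!is.null(truth)) {
    keep_cells <- match(jp$cell_ids, truth$profile$cell_ids)
    keep_genes <- match(jp$gene_ids, truth$profile$gene_ids)
    im <- imputation_metrics(imp$imputed_rna,
                             truth$true_rna_means[keep_cells, keep_genes, drop = FALSE],
                             raw = as.matrix(jp$rna_counts))
    metrics$rna_imputation_win_rate <- mean(im$imputed_wins, na.rm = TRUE)
  }

  stage("write", {
    write_outputs(embedding, imp$imputed_rna, imp$imputed_atac, out_dir,
                  cell_ids = jp$cell_ids, gene_ids = jp$gene_ids,
                  peak_ids = jp$peak_ids)
    utils::write.table(data.frame(cell = jp$cell_ids, cluster = cl$assignments),
                       file.path(out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(fit$losses), file.path(out_dir, "losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    save_checkpoint(fit$model, file.path(out_dir, "checkpoint.rds"))
  })
  manifest <- list(package_version = as.character(utils::packageVersion("duetvae")),
                   r_version = R.version.string,
                   seed = seed, k = k,
                   n_cells = length(jp$cell_ids),
                   n_genes = length(jp$gene_ids),
                   n_peaks = length(jp$peak_ids),
                   model_config = unclass(mcfg), train_config = unclass(tcfg),
                   metrics = metrics[c("ari", "final_loss_per_cell")])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(fit = fit, clustering = cl, metrics = metrics,
                 manifest = manifest))
}

# Minimal key=value / "key: value" config reader (one key per line; numeric
# values auto-converted).
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("[:=]", "\1", ln), "\1", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1L]); v <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(v))
    out[[key]] <- if (!is.na(num)) num else v
  }
  out
}
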