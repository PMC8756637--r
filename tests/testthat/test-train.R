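# Training loop: determinism, batching arithmetic, loss behaviour.

test_that("identical seeds give identical loss tables; different seeds differ", {
  sim <- small_sim(seed = 17L, n_cells = 90L)
  cfg <- small_config()
  tcfg <- train_config(batch_size = 45L, max_epochs = 4L, warmup_epochs = 2L,
                       seed = 5L)
  f1 <- train_duet(sim$profile, cfg, tcfg)
  f2 <- train_duet(sim$profile, cfg, tcfg)
  expect_equal(f1$losses$total, f2$losses$total, tolerance = 1e-9)
  p1 <- encode_joint(f1$model, as.matrix(sim$profile$rna_counts),
                     as.matrix(tfidf_transform(sim$profile$atac_counts)))
  p2 <- encode_joint(f2$model, as.matrix(sim$profile$rna_counts),
                     as.matrix(tfidf_transform(sim$profile$atac_counts)))
  expect_equal(p1$mu_z, p2$mu_z, tolerance = 1e-9)
  f3 <- train_duet(sim$profile, cfg,
                   train_config(batch_size = 45L, max_epochs = 4L,
                                warmup_epochs = 2L, seed = 6L))
  expect_false(isTRUE(all.equal(f1$losses$total, f3$losses$total)))
})

test_that("batch_size >= n gives exactly one optimizer step per epoch", {
  sim <- small_sim(seed = 18L, n_cells = 40L)
  # one step per epoch means the whole batch statistics are used once:
  # verify via the loss table row count and that training still runs
  fit <- train_duet(sim$profile, small_config(),
                    train_config(batch_size = 64L, max_epochs = 3L,
                                 warmup_epochs = 1L, seed = 2L))
  expect_identical(nrow(fit$losses), 3L)
})

test_that("training reduces the total loss on an easy fixture", {
  sim <- small_sim(seed = 19L, n_cells = 120L)
  fit <- train_duet(sim$profile, small_config(),
                    train_config(batch_size = 60L, max_epochs = 12L,
                                 warmup_epochs = 3L, seed = 3L))
  main <- fit$losses[fit$losses$phase == "main", ]
  expect_lt(main$total[nrow(main)], main$total[1])
  # loss-report identity: total = nll_rna + nll_atac + kl_prior + lambda * kl_consistency
  with(fit$losses, expect_equal(total,
                                nll_rna + nll_atac + kl_prior + kl_consistency,
                                tolerance = 1e-9))
})

test_that("lambda = 0 removes the consistency term from the total but still reports it", {
  sim <- small_sim(seed = 23L, n_cells = 60L)
  cfg <- small_config()
  cfg$lambda_consistency <- 0
  fit <- train_duet(sim$profile, cfg,
                    train_config(batch_size = 30L, max_epochs = 3L,
                                 warmup_epochs = 1L, seed = 4L))
  expect_true(all(fit$losses$kl_consistency >= 0))
  expect_equal(fit$losses$total,
               fit$losses$nll_rna + fit$losses$nll_atac + fit$losses$kl_prior,
               tolerance = 1e-9)
})

test_that("single-modality training runs and encodes", {
  sim <- small_sim(seed = 27L, n_cells = 60L)
  for (mod in c("rna", "atac")) {
    cfg <- small_config()
    cfg$modality <- mod
    fit <- train_duet(sim$profile, cfg,
                      train_config(batch_size = 30L, max_epochs = 3L,
                                   warmup_epochs = 1L, seed = 4L))
    post <- if (mod == "rna") {
      encode_joint(fit$model, x = as.matrix(sim$profile$rna_counts))
    } else {
      encode_joint(fit$model,
                   y = as.matrix(tfidf_transform(sim$profile$atac_counts)))
    }
    expect_identical(nrow(post$mu_z), 60L)
    if (mod == "rna") expect_true(all(fit$losses$nll_atac == 0))
    if (mod == "atac") expect_true(all(fit$losses$nll_rna == 0))
  }
})

test_that("empty data and invalid configs are rejected", {
  expect_error(train_config(warmup_epochs = 30, max_epochs = 30))
  expect_error(train_config(batch_size = 0))
  sim <- small_sim(seed = 28L, n_cells = 20L)
  expect_error(train_duet(sim$profile, "not a config", train_config()))
})

test_that("tidy/glance/autoplot work on a fit", {
  sim <- small_sim(seed = 29L, n_cells = 40L)
  fit <- train_duet(sim$profile, small_config(),
                    train_config(batch_size = 40L, max_epochs = 3L,
                                 warmup_epochs = 1L, seed = 1L))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$term),
                  c("nll_rna", "nll_atac", "kl_prior", "kl_consistency",
                    "kl_raw", "total"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$epochs, 3L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_embedding(matrix(rnorm(80), 40), sim$true_labels),
                  "ggplot")
})

test_that("run_pipeline produces all declared artifacts and is reproducible", {
  out1 <- withr::local_tempdir()
  cfgL <- list(sim = sim_spec(n_cells = 60, n_genes = 30, n_peaks = 50,
                              K_true = 2, seed = 12),
               k = 2, seed = 3, out_dir = out1,
               model = list(latent_dim = 4, hidden_dim = 16, shared_dim = 32,
                            n_heads = 2, head_dim = 8),
               train = list(batch_size = 30, max_epochs = 3, warmup_epochs = 1))
  res <- run_pipeline(cfgL)
  for (f in c("embedding.tsv", "clusters.tsv", "losses.tsv", "manifest.json",
              "checkpoint.rds", "imputed_rna/matrix.mtx",
              "imputed_atac/matrix.mtx")) {
    expect_true(file.exists(file.path(out1, f)), info = f)
  }
  out2 <- withr::local_tempdir()
  cfgL$out_dir <- out2
  res2 <- run_pipeline(cfgL)
  expect_equal(res$metrics$ari, res2$metrics$ari, tolerance = 1e-9)
  expect_equal(res$fit$losses$total, res2$fit$losses$total, tolerance = 1e-9)
  # missing k with no labels errors
  cfgNoK <- list(sim = sim_spec(n_cells = 30, n_genes = 10, n_peaks = 20,
                                K_true = 2, seed = 1),
                 seed = 1, out_dir = withr::local_tempdir())
  cfgNoK$sim$seed <- 1
  # simulated profiles carry labels, so strip them by building a config that
  # reads from disk instead
  d <- withr::local_tempdir()
  sim <- small_sim(seed = 30L, n_cells = 30L)
  duetvae:::write_triplet(sim$profile$rna_counts, sim$profile$gene_ids,
                          sim$profile$cell_ids, file.path(d, "rna"))
  duetvae:::write_triplet(sim$profile$atac_counts, sim$profile$peak_ids,
                          sim$profile$cell_ids, file.path(d, "atac"))
  expect_error(suppressMessages(run_pipeline(list(rna_path = file.path(d, "rna"),
                                                  atac_path = file.path(d, "atac"),
                                                  seed = 1,
                                                  out_dir = withr::local_tempdir()))),
               "config\\$k")
})
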