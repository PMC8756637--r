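# Readers/writers, filtering rules and the TF-IDF transform.

test_that("joint_profile validates shapes, ids and integrality", {
  expect_error(joint_profile(matrix(1L, 2, 3), matrix(1L, 3, 3)),
               "disagree on cell count")
  expect_error(joint_profile(matrix(-1, 2, 2), matrix(1L, 2, 2)),
               "non-negative integers")
  expect_error(joint_profile(matrix(0.5, 2, 2), matrix(1L, 2, 2)),
               "non-negative integers")
  expect_error(joint_profile(matrix(1L, 2, 2), matrix(1L, 2, 2),
                             cell_ids = c("a", "a")), "duplicate")
})

test_that("triplet round trip preserves counts, ordering and ids", {
  sim <- small_sim(seed = 3L, n_cells = 30L)
  jp <- sim$profile
  d <- withr::local_tempdir()
  write_triplet_dirs <- function(jp, root) {
    duetvae:::write_triplet(jp$rna_counts, jp$gene_ids, jp$cell_ids,
                            file.path(root, "rna"))
    duetvae:::write_triplet(jp$atac_counts, jp$peak_ids, jp$cell_ids,
                            file.path(root, "atac"))
  }
  write_triplet_dirs(jp, d)
  jp2 <- suppressMessages(read_joint_profile(file.path(d, "rna"),
                                             file.path(d, "atac")))
  expect_identical(jp2$cell_ids, jp$cell_ids)
  expect_identical(jp2$gene_ids, jp$gene_ids)
  expect_identical(jp2$peak_ids, jp$peak_ids)
  expect_equal(as.matrix(jp2$rna_counts), as.matrix(jp$rna_counts),
               ignore_attr = TRUE)
  expect_equal(as.matrix(jp2$atac_counts), as.matrix(jp$atac_counts),
               ignore_attr = TRUE)
})

test_that("barcode intersection keeps RNA order and reports drops", {
  d <- withr::local_tempdir()
  rna <- matrix(1:9, 3, 3, dimnames = list(NULL, NULL))
  atac <- matrix(1:9, 3, 3)
  duetvae:::write_triplet(Matrix::Matrix(rna, sparse = TRUE),
                          paste0("g", 1:3), c("A", "B", "C"),
                          file.path(d, "rna"))
  duetvae:::write_triplet(Matrix::Matrix(atac, sparse = TRUE),
                          paste0("p", 1:3), c("B", "C", "D"),
                          file.path(d, "atac"))
  expect_message(jp <- read_joint_profile(file.path(d, "rna"),
                                          file.path(d, "atac")),
                 "1 dropped from RNA, 1 from ATAC")
  expect_identical(jp$cell_ids, c("B", "C"))
  # zero overlap errors
  duetvae:::write_triplet(Matrix::Matrix(atac, sparse = TRUE),
                          paste0("p", 1:3), c("X", "Y", "Z"),
                          file.path(d, "atac2"))
  expect_error(suppressMessages(read_joint_profile(file.path(d, "rna"),
                                                   file.path(d, "atac2"))),
               "zero overlapping")
  expect_error(read_joint_profile(file.path(d, "nope"), file.path(d, "atac")),
               "nope")
})

test_that("negative or fractional entries on disk are rejected", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(1, -1, 2, 3), 2, 2), sparse = TRUE)
  duetvae:::write_triplet(m, c("g1", "g2"), c("A", "B"), file.path(d, "bad"))
  expect_error(duetvae:::read_modality(file.path(d, "bad")), "negative")
})

test_that("filtering applies cells-then-features exactly once", {
  jp <- toy_profile()
  # cell c3 detects 2 genes (g1, g4): with threshold 2 it survives on RNA
  # but let's use the documented toy: cell with 1 nonzero gene dropped
  rna <- rbind(c(5L, 2L, 1L, 0L),
               c(3L, 1L, 2L, 0L),
               c(4L, 0L, 0L, 1L)) # c3: 2 nonzero genes? -> g1,g4
  rna[3, 1] <- 0L # now c3 has only g4: 1 nonzero gene
  atac <- matrix(1L, 3, 4)
  jp <- joint_profile(rna, atac, cell_ids = c("c1", "c2", "c3"),
                      gene_ids = paste0("g", 1:4), peak_ids = paste0("p", 1:4))
  out <- filter_joint_profile(jp, filter_spec(min_features_per_cell = 2,
                                              min_cells_per_feature = 2))
  expect_identical(out$cell_ids, c("c1", "c2"))
  # g4 nonzero only in dropped c3 -> gone; g2 nonzero in 2 cells -> kept
  expect_identical(out$gene_ids, c("g1", "g2", "g3"))
  # thresholds 0 are a no-op
  same <- filter_joint_profile(jp, filter_spec(0, 0))
  expect_identical(same$cell_ids, jp$cell_ids)
  expect_identical(same$gene_ids, jp$gene_ids)
  expect_equal(as.matrix(same$rna_counts), as.matrix(jp$rna_counts),
               ignore_attr = TRUE)
})

test_that("max_cells_per_peak removes ubiquitous peaks", {
  rna <- matrix(2L, 3, 3)
  atac <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L))
  jp <- joint_profile(rna, atac)
  out <- filter_joint_profile(jp, filter_spec(1, 1, max_cells_per_peak = 2))
  expect_identical(out$peak_ids, c("peak2", "peak3"))
  expect_error(filter_spec(1, 5, max_cells_per_peak = 4), "must exceed")
})

test_that("filtering is idempotent on stable fixtures and errors when everything dies", {
  sim <- small_sim(seed = 8L, n_cells = 50L)
  spec <- filter_spec(min_features_per_cell = 5, min_cells_per_feature = 3)
  once <- filter_joint_profile(sim$profile, spec)
  twice <- filter_joint_profile(once, spec)
  expect_identical(twice$cell_ids, once$cell_ids)
  expect_identical(twice$gene_ids, once$gene_ids)
  expect_identical(twice$peak_ids, once$peak_ids)
  expect_error(filter_joint_profile(sim$profile,
                                    filter_spec(10000, 1)),
               "removed all")
})

test_that("tfidf_transform matches the hand-worked formula", {
  m <- rbind(c(1L, 0L), c(1L, 1L))
  out <- as.matrix(tfidf_transform(m))
  # df = (2, 1); IDF = log(1 + 2/2), log(1 + 2/1); cell 1 has 1 nonzero peak
  expect_equal(out[1, ], c(1e4 * log(2), 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(out[2, ], c(0.5e4 * log(2), 0.5e4 * log(3)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # counts above 1 are binarised: same output
  m2 <- rbind(c(7L, 0L), c(2L, 9L))
  expect_equal(as.matrix(tfidf_transform(m2)), out, tolerance = 1e-12)
})

test_that("tfidf zero set equals the input zero set; all-present peak is constant", {
  sim <- small_sim(seed = 5L, n_cells = 40L)
  a <- as.matrix(sim$profile$atac_counts)
  tf <- as.matrix(tfidf_transform(a))
  expect_identical(tf == 0, a == 0)
  expect_true(all(is.finite(tf)) && all(tf >= 0))
  # single-peak cells with an everywhere-present peak: all entries equal
  m <- matrix(1L, 4, 1)
  out <- as.matrix(tfidf_transform(m))
  expect_equal(as.numeric(out), rep(1e4 * log(2), 4), tolerance = 1e-12)
  # all-zero cell is an error
  expect_error(tfidf_transform(rbind(c(1L, 1L), c(0L, 0L))), "no nonzero")
})

test_that("tfidf_inverse undoes the IDF weighting back to term-frequency units", {
  sim <- small_sim(seed = 6L, n_cells = 30L)
  a <- as.matrix(sim$profile$atac_counts)
  tf <- tfidf_transform(a)
  back <- tfidf_inverse(tf, a)
  b <- a > 0
  want <- b / rowSums(b)
  expect_equal(back, want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(tfidf_inverse(as.matrix(tf)[, 1:3], a), "mismatch")
})

test_that("write_outputs round-trips the embedding and validates inputs", {
  d <- withr::local_tempdir()
  set.seed(2)
  emb <- matrix(rnorm(12), 4, 3)
  imp_r <- matrix(runif(8), 4, 2)
  imp_a <- matrix(runif(12), 4, 3)
  write_outputs(emb, imp_r, imp_a, d, cell_ids = paste0("c", 1:4))
  back <- read_embedding(file.path(d, "embedding.tsv"))
  expect_equal(back$embedding, emb, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$cell_ids, paste0("c", 1:4))
  expect_true(dir.exists(file.path(d, "imputed_rna")))
  expect_error(write_outputs(emb[0, , drop = FALSE], NULL, NULL, d), "empty")
  expect_error(write_outputs(emb, -imp_r, NULL, d), "negative")
})
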