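# Paired-profile container, 10x-style triplet / dense-table readers,
# cell/feature filtering and the TF-IDF transform of the peak matrix.

#' Construct a paired RNA + ATAC profile
#'
#' Holds a cells x genes and a cells x peaks raw count matrix measured in
#' the same cells, with aligned cell identifiers. Matrices are stored as
#' sparse `dgCMatrix`.
#'
#' @param rna_counts Cells x genes non-negative integer matrix.
#' @param atac_counts Cells x peaks non-negative integer matrix.
#' @param cell_ids,gene_ids,peak_ids Unique identifier vectors. Peak IDs
#'   conventionally look like `"chr1:500-900"` but are never parsed.
#' @param labels Optional per-cell category labels (evaluation only).
#' @param atac_tfidf Optional precomputed TF-IDF matrix (same shape as
#'   `atac_counts`, zero exactly where the counts are zero).
#' @return An object of class `joint_profile`.
#' @export
joint_profile <- function(rna_counts, atac_counts, cell_ids = NULL,
                          gene_ids = NULL, peak_ids = NULL, labels = NULL,
                          atac_tfidf = NULL) {
  rna_counts <- methods::as(methods::as(rna_counts, "CsparseMatrix"), "generalMatrix")
  atac_counts <- methods::as(methods::as(atac_counts, "CsparseMatrix"), "generalMatrix")
  n <- nrow(rna_counts)
  if (nrow(atac_counts) != n) stop("RNA and ATAC matrices disagree on cell count")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(rna_counts)))
  if (is.null(peak_ids)) peak_ids <- paste0("peak", seq_len(ncol(atac_counts)))
  if (length(cell_ids) != n) stop("cell_ids length does not match the matrices")
  if (length(gene_ids) != ncol(rna_counts)) stop("gene_ids length mismatch")
  if (length(peak_ids) != ncol(atac_counts)) stop("peak_ids length mismatch")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(peak_ids)) stop("duplicate peak_ids")
  for (m in list(rna = rna_counts, atac = atac_counts)) {
    v <- m@x
    if (length(v) && (any(v < 0) || any(v != round(v)))) {
      stop("count matrices must hold non-negative integers")
    }
  }
  if (!is.null(labels) && length(labels) != n) stop("labels length mismatch")
  if (!is.null(atac_tfidf)) {
    atac_tfidf <- methods::as(methods::as(atac_tfidf, "CsparseMatrix"), "generalMatrix")
    if (!identical(dim(atac_tfidf), dim(atac_counts))) {
      stop("atac_tfidf must have the same shape as atac_counts")
    }
  }
  structure(list(rna_counts = rna_counts, atac_counts = atac_counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 peak_ids = as.character(peak_ids),
                 labels = labels, atac_tfidf = atac_tfidf),
            class = "joint_profile")
}

#' @export
print.joint_profile <- function(x, ...) {
  cat(sprintf("joint_profile: %d cells, %d genes, %d peaks%s%s\n",
              length(x$cell_ids), length(x$gene_ids), length(x$peak_ids),
              if (!is.null(x$labels)) ", labelled" else "",
              if (!is.null(x$atac_tfidf)) ", TF-IDF cached" else ""))
  invisible(x)
}

# Read one modality: either a 10x triplet directory (matrix.mtx +
# features.tsv + barcodes.tsv, optionally gzipped) or a dense delimited
# table with a header row of cell IDs and a first column of feature IDs.
# Returns cells x features sparse matrix with dimnames.
read_modality <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    find1 <- function(stem) {
      for (f in c(stem, paste0(stem, ".gz"))) {
        fp <- file.path(path, f)
        if (file.exists(fp)) return(fp)
      }
      stop("missing ", stem, " (or .gz) in ", path)
    }
    m <- Matrix::readMM(find1("matrix.mtx"))
    feats <- utils::read.delim(find1("features.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    bcs <- utils::read.delim(find1("barcodes.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(feats) || ncol(m) != length(bcs)) {
      stop("matrix dimensions disagree with features/barcodes tables in ", path)
    }
    m <- Matrix::t(m) # stored features x barcodes; we want cells in rows
    dimnames(m) <- list(bcs, feats)
  } else {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                             sep = if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t",
                             check.names = FALSE)
    m <- Matrix::t(Matrix::Matrix(as.matrix(tab), sparse = TRUE))
  }
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("non-integer or negative entries in ", path)
  }
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Read a paired profile from disk
#'
#' Each path is a 10x-style triplet directory (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, gzip tolerated) or a dense delimited table (features in
#' rows, cells in columns). Cells are the intersection of the two barcode
#' sets, kept in the RNA file's order; the number of cells dropped from each
#' side is reported with a message.
#'
#' @param rna_path,atac_path Paths to the two modalities.
#' @return A [joint_profile()].
#' @export
read_joint_profile <- function(rna_path, atac_path) {
  rna <- read_modality(rna_path)
  atac <- read_modality(atac_path)
  common <- rownames(rna)[rownames(rna) %in% rownames(atac)]
  if (length(common) == 0L) stop("zero overlapping cell barcodes between modalities")
  message(sprintf("barcode intersection: %d cells kept; %d dropped from RNA, %d from ATAC",
                  length(common), nrow(rna) - length(common),
                  nrow(atac) - length(common)))
  joint_profile(rna[common, , drop = FALSE], atac[common, , drop = FALSE],
                cell_ids = common, gene_ids = colnames(rna),
                peak_ids = colnames(atac))
}

#' Filtering thresholds for cells and features
#'
#' Defaults mirror common joint-profiling practice: drop cells detecting
#' fewer than 200 genes or fewer than 200 peaks, then drop features detected
#' in fewer than 10 of the surviving cells. `max_cells_per_peak` optionally
#' removes ubiquitously open peaks.
#'
#' @param min_features_per_cell Minimum nonzero genes AND nonzero peaks per
#'   cell.
#' @param min_cells_per_feature Minimum cells in which a gene/peak is
#'   nonzero.
#' @param max_cells_per_peak Optional upper bound on cells per peak.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_features_per_cell = 200L,
                        min_cells_per_feature = 10L,
                        max_cells_per_peak = NULL) {
  stopifnot(min_features_per_cell >= 0, min_cells_per_feature >= 0)
  if (!is.null(max_cells_per_peak) &&
      max_cells_per_peak <= min_cells_per_feature) {
    stop("max_cells_per_peak must exceed min_cells_per_feature")
  }
  structure(list(min_features_per_cell = as.integer(min_features_per_cell),
                 min_cells_per_feature = as.integer(min_cells_per_feature),
                 max_cells_per_peak = if (is.null(max_cells_per_peak)) NULL
                                      else as.integer(max_cells_per_peak)),
            class = "filter_spec")
}

#' Filter a paired profile
#'
#' Single pass, cells first: (1) remove cells whose nonzero-gene count or
#' nonzero-peak count is below `min_features_per_cell`; (2) on the surviving
#' cells, remove genes and peaks nonzero in fewer than
#' `min_cells_per_feature` cells; (3) if set, remove peaks nonzero in more
#' than `max_cells_per_peak` cells. Not iterated to a fixpoint.
#'
#' @param jp A [joint_profile()].
#' @param spec A [filter_spec()].
#' @return A new, filtered [joint_profile()].
#' @export
filter_joint_profile <- function(jp, spec = filter_spec()) {
  stopifnot(inherits(jp, "joint_profile"), inherits(spec, "filter_spec"))
  genes_per_cell <- Matrix::rowSums(jp$rna_counts > 0)
  peaks_per_cell <- Matrix::rowSums(jp$atac_counts > 0)
  keep_cells <- genes_per_cell >= spec$min_features_per_cell &
    peaks_per_cell >= spec$min_features_per_cell
  if (!any(keep_cells)) {
    stop(sprintf("filtering removed all %d cells (thresholds: >= %d nonzero genes and peaks)",
                 length(keep_cells), spec$min_features_per_cell))
  }
  rna <- jp$rna_counts[keep_cells, , drop = FALSE]
  atac <- jp$atac_counts[keep_cells, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(rna > 0)
  cells_per_peak <- Matrix::colSums(atac > 0)
  keep_genes <- cells_per_gene >= spec$min_cells_per_feature
  keep_peaks <- cells_per_peak >= spec$min_cells_per_feature
  if (!is.null(spec$max_cells_per_peak)) {
    keep_peaks <- keep_peaks & cells_per_peak <= spec$max_cells_per_peak
  }
  if (!any(keep_genes) || !any(keep_peaks)) {
    stop(sprintf("filtering removed all features of one modality (%d/%d genes, %d/%d peaks kept)",
                 sum(keep_genes), length(keep_genes),
                 sum(keep_peaks), length(keep_peaks)))
  }
  joint_profile(rna[, keep_genes, drop = FALSE],
                atac[, keep_peaks, drop = FALSE],
                cell_ids = jp$cell_ids[keep_cells],
                gene_ids = jp$gene_ids[keep_genes],
                peak_ids = jp$peak_ids[keep_peaks],
                labels = if (!is.null(jp$labels)) jp$labels[keep_cells])
}

#' TF-IDF transform of the peak matrix
#'
#' Converts binary peak presence into continuous rarity-weighted values:
#' counts are binarised to presence `b`, the term frequency is
#' `b / (nonzero peaks in the cell)`, the inverse document frequency is
#' `log(1 + n_cells / cells_with_peak)`, and the product is multiplied by
#' `scale`. Zeros are preserved exactly.
#'
#' @param atac_counts Cells x peaks non-negative matrix (dense or sparse).
#' @param scale Output scale factor.
#' @return Sparse cells x peaks matrix of TF-IDF values.
#' @export
tfidf_transform <- function(atac_counts, scale = 1e4) {
  m <- methods::as(methods::as(atac_counts, "CsparseMatrix"), "generalMatrix")
  if (length(m@x) && any(m@x < 0)) stop("atac counts must be non-negative")
  b <- m
  b@x <- rep(1, length(b@x))
  b <- Matrix::drop0(b)
  peaks_per_cell <- Matrix::rowSums(b)
  if (any(peaks_per_cell == 0)) {
    stop(sum(peaks_per_cell == 0), " cell(s) have no nonzero peaks; filter first")
  }
  cells_per_peak <- Matrix::colSums(b)
  idf <- log(1 + nrow(b) / pmax(cells_per_peak, 1))
  tf <- b / peaks_per_cell
  out <- Matrix::t(Matrix::t(tf) * idf) * scale
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Map TF-IDF-scale values back to the accessibility scale
#'
#' Divides a matrix that lives on the TF-IDF output scale (e.g. imputed ZIP
#' means) by the per-peak IDF weights and the scale factor, recovering
#' term-frequency units (presence weight per detected peak). Use this before
#' comparing imputed ATAC signal against accessibility rates: the IDF factor
#' deliberately down-weights ubiquitous peaks, which are exactly the
#' high-rate ones, so rate-scale comparisons on raw TF-IDF output are
#' confounded.
#'
#' @param values Cells x peaks matrix on the TF-IDF scale.
#' @param atac_counts The raw count matrix the TF-IDF transform was computed
#'   from (used to recompute the per-peak document frequencies).
#' @param scale The scale factor used by [tfidf_transform()].
#' @return Matrix of the same shape in term-frequency units.
#' @export
tfidf_inverse <- function(values, atac_counts, scale = 1e4) {
  values <- as.matrix(values)
  b <- as.matrix(atac_counts) > 0
  if (!identical(dim(values), dim(b))) stop("shape mismatch with atac_counts")
  idf <- log(1 + nrow(b) / pmax(colSums(b), 1))
  sweep(values, 2L, idf * scale, "/")
}

# Write a sparse matrix as a triplet directory (matrix.mtx features/barcodes
# tsv), cells in rows on the R side, features x cells on disk.
write_triplet <- function(m, features, barcodes, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(features), file.path(dir_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(barcodes), file.path(dir_path, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir_path)
}

#' Write embedding and imputed matrices to an output directory
#'
#' The embedding is written as `embedding.tsv` (cell column + `z_1..z_D`, 6
#' decimal places); imputed matrices as matrix-market triplet directories
#' `imputed_rna/` and `imputed_atac/`.
#'
#' @param embedding Cells x D real matrix.
#' @param imputed_rna,imputed_atac Cells x features non-negative matrices
#'   (either may be `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param cell_ids,gene_ids,peak_ids Identifier vectors.
#' @return Invisibly, the vector of paths written.
#' @export
write_outputs <- function(embedding, imputed_rna, imputed_atac, out_dir,
                          cell_ids = NULL, gene_ids = NULL, peak_ids = NULL) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) == 0L) stop("empty embedding: no cells to write")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(embedding)))
  if (length(cell_ids) != nrow(embedding)) stop("cell_ids length mismatch")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  df <- data.frame(cell = cell_ids,
                   formatC(embedding, format = "f", digits = 6))
  names(df) <- c("cell", paste0("z_", seq_len(ncol(embedding))))
  ep <- file.path(out_dir, "embedding.tsv")
  utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, ep)
  for (nm in c("imputed_rna", "imputed_atac")) {
    m <- if (nm == "imputed_rna") imputed_rna else imputed_atac
    if (is.null(m)) next
    if (nrow(m) != nrow(embedding)) stop(nm, " row count disagrees with embedding")
    if (any(m < 0)) stop(nm, " has negative entries; imputed means must be >= 0")
    feats <- if (nm == "imputed_rna") gene_ids else peak_ids
    if (is.null(feats)) feats <- paste0("f", seq_len(ncol(m)))
    paths <- c(paths, write_triplet(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                                    feats, cell_ids, file.path(out_dir, nm)))
  }
  invisible(paths)
}

#' Read back an embedding table written by [write_outputs()]
#'
#' @param path Path to `embedding.tsv`.
#' @return List with `cell_ids` and the numeric `embedding` matrix.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  list(cell_ids = tab[[1L]], embedding = as.matrix(tab[, -1L, drop = FALSE]))
}
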