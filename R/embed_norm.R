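#' Log-normalize a count matrix
#'
#' Per cell: `ln(1 + count * scale_total / cell_total)`. Cells with zero
#' total counts map to all-zero columns. The result stays sparse.
#'
#' @param m a [count_matrix()].
#' @param scale_total target library size (default 10,000).
#' @return object of class `normalized_matrix` with fields `values`
#'   (sparse genes x cells), `gene_ids`, `gene_symbols`, `barcodes`.
#' @export
log_normalize <- function(m, scale_total = 1e4) {
  validate_count_matrix(m)
  if (scale_total <= 0) stop_validation("scale_total must be > 0")
  v <- m$values
  totals <- Matrix::colSums(v)
  sf <- ifelse(totals > 0, scale_total / totals, 0)
  if (length(v@x))
    v@x <- log1p(v@x * rep.int(sf, diff(v@p)))
  structure(list(values = v, gene_ids = m$gene_ids,
                 gene_symbols = m$gene_symbols, barcodes = m$barcodes),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Row means and (n-1)-denominator variances of a sparse matrix.
row_mean_var <- function(v) {
  n <- ncol(v)
  mu <- Matrix::rowSums(v) / n
  ssq <- Matrix::rowSums(v^2)
  var <- (ssq - n * mu^2) / (n - 1)
  var[var < 0] <- 0  # numerical floor
  list(mean = mu, var = var)
}

#' Select highly variable genes
#'
#' Mean/dispersion binning: genes are binned into `n_bins` equal-width bins
#' of log mean expression (computed on de-logged normalized values), and
#' within each bin the log dispersion (variance/mean) is z-scored; the top
#' `n_top` genes by z-score are returned. Deterministic; ties are broken by
#' input gene order. Genes with zero mean or zero variance are never ranked
#' ahead of any gene with positive dispersion.
#'
#' @param nm a [log_normalize()] result.
#' @param n_top number of genes to return (clamped to the gene count).
#' @param n_bins number of equal-width log-mean bins.
#' @return character vector of gene ids, ranked.
#' @export
select_hvgs <- function(nm, n_top = 2000, n_bins = 20) {
  if (n_top < 1) stop_validation("n_top must be >= 1")
  v <- nm$values
  ve <- v
  if (length(ve@x)) ve@x <- expm1(ve@x)
  mv <- row_mean_var(ve)
  ok <- mv$mean > 0 & mv$var > 0
  z <- rep(-Inf, nrow(v))
  if (any(ok)) {
    lm <- log(mv$mean[ok])
    ld <- log(mv$var[ok] / mv$mean[ok])
    bins <- cut(lm, breaks = n_bins, include.lowest = TRUE)
    mu_b <- tapply(ld, bins, mean)
    sd_b <- tapply(ld, bins, stats::sd)
    n_b <- tapply(ld, bins, length)
    # under-occupied bins carry no within-bin information: fall back to the
    # global dispersion statistics there
    sparse_bin <- is.na(n_b) | n_b < 2
    mu_b[sparse_bin] <- mean(ld)
    sd_b[sparse_bin] <- stats::sd(ld)
    zb <- (ld - mu_b[bins]) / sd_b[bins]
    zb[!is.finite(zb)] <- 0  # constant bins / constant dispersion
    z[ok] <- zb
  }
  ord <- order(-z)  # stable: ties keep input order
  nm$gene_ids[ord[seq_len(min(n_top, nrow(v)))]]
}

#' Scale and center selected genes
#'
#' Per gene: subtract the mean across cells and divide by the sample
#' standard deviation (n-1 denominator); zero-variance genes map to all
#' zeros; values are clipped to `[-clip, clip]`.
#'
#' @param nm a [log_normalize()] result.
#' @param genes gene ids to scale (subset of `nm$gene_ids`).
#' @param clip clipping bound (default 10).
#' @return dense genes x cells matrix (rownames = gene ids).
#' @export
scale_center <- function(nm, genes = nm$gene_ids, clip = 10) {
  if (clip <= 0) stop_validation("clip must be > 0")
  idx <- match(genes, nm$gene_ids)
  if (anyNA(idx))
    stop_validation(sprintf("genes not present in matrix: %s",
                            paste(utils::head(genes[is.na(idx)], 3), collapse = ", ")))
  x <- as.matrix(nm$values[idx, , drop = FALSE])
  mu <- rowMeans(x)
  n <- ncol(x)
  sdv <- sqrt(pmax(rowSums(x^2) - n * mu^2, 0) / (n - 1))
  out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  rownames(out) <- genes
  colnames(out) <- nm$barcodes
  out
}

#' PCA embedding of cells
#'
#' Principal-component scores of cells on the top-K components of the
#' gene-centered scaled matrix, computed by SVD (deterministic; the seed
#' argument is accepted for interface stability but unused). The sign of
#' each component is fixed so that the loading entry of largest magnitude
#' is non-negative. `explained_variance` is non-increasing.
#'
#' @param scaled dense genes x cells matrix from [scale_center()].
#' @param K number of components (default 20, the study's retained count).
#' @param seed unused; kept so pipelines can thread one seed everywhere.
#' @return object of class `sc_embedding`: `coords` (cells x K,
#'   rownames = barcodes), `explained_variance` (length K), `K`.
#' @export
pca_embed <- function(scaled, K = 20, seed = 0L) {
  if (K < 1) stop_validation("K must be >= 1")
  X <- t(scaled)  # cells x genes
  feasible <- min(dim(X))
  if (K > feasible)
    stop_validation(sprintf("K = %d exceeds feasible maximum %d (min of cells, genes)",
                            K, feasible))
  X <- sweep(X, 2, colMeans(X))  # genes centered across cells
  sv <- svd(X, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  scores <- sv$u %*% diag(d, K, K)
  loadings <- sv$v
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(K))
  embedding(scores, explained_variance = d^2 / (nrow(X) - 1))
}

#' Construct an embedding object
#'
#' Light container for cells x K coordinates, used both by [pca_embed()]
#' and for externally supplied embeddings.
#'
#' @param coords numeric cells x K matrix with barcode rownames.
#' @param explained_variance optional non-increasing variance vector.
#' @return object of class `sc_embedding`.
#' @export
embedding <- function(coords, explained_variance = NULL) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords)))
    stop_validation("embedding coords need barcode rownames")
  if (!is.null(explained_variance) &&
      is.unsorted(-explained_variance, strictly = FALSE))
    stop_validation("explained_variance must be non-increasing")
  structure(list(coords = coords, explained_variance = explained_variance,
                 K = ncol(coords)),
            class = "sc_embedding")
}

#' @export
print.sc_embedding <- function(x, ...) {
  cat(sprintf("sc_embedding: %d cells x %d PCs\n", nrow(x$coords), x$K))
  invisible(x)
}

#' Write an embedding as TSV (barcode + one column per PC)
#' @param emb an `sc_embedding`.
#' @param path output file.
#' @export
write_embedding_tsv <- function(emb, path) {
  df <- data.frame(barcode = rownames(emb$coords), emb$coords,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
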