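# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# 3-gene x 2-cell toy matrix with entries (g1,c1)=5, (g3,c2)=1.
tiny_cm <- function() {
  v <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 1),
                            dims = c(3, 2))
  count_matrix(v, gene_ids = c("g1", "g2", "g3"),
               gene_symbols = c("S1", "MT-CO1", "RPS9"),
               barcodes = c("c1", "c2"))
}

# Random sparse integer count matrix with some organelle symbols.
random_cm <- function(n_genes = 50, n_cells = 20, density = 0.3, seed = 1) {
  set.seed(seed)
  nnz <- round(n_genes * n_cells * density)
  ij <- unique(cbind(sample(n_genes, nnz, TRUE), sample(n_cells, nnz, TRUE)))
  v <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                            x = rpois(nrow(ij), 3) + 1,
                            dims = c(n_genes, n_cells))
  syms <- sprintf("G%03d", seq_len(n_genes))
  n_org <- max(2, round(n_genes * 0.1))
  syms[seq_len(n_org %/% 2)] <- paste0("MT-", seq_len(n_org %/% 2))
  syms[(n_org %/% 2 + 1):n_org] <- paste0("RPS", seq_len(n_org - n_org %/% 2))
  count_matrix(v, gene_ids = sprintf("ENSG%03d", seq_len(n_genes)),
               gene_symbols = syms,
               barcodes = sprintf("BC%03d", seq_len(n_cells)))
}

# Build a count matrix cell-by-cell from a list of (gene index -> count)
# vectors; genes beyond `n_org_mito`+`n_org_ribo` are plain.
cm_from_columns <- function(cols, n_genes, n_mito = 0, n_ribo = 0) {
  i <- unlist(lapply(cols, function(cl) cl$i))
  j <- rep.int(seq_along(cols), vapply(cols, function(cl) length(cl$i), integer(1)))
  x <- unlist(lapply(cols, function(cl) cl$x))
  v <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(n_genes, length(cols)))
  syms <- sprintf("G%05d", seq_len(n_genes))
  if (n_mito > 0) syms[seq_len(n_mito)] <- paste0("MT-", seq_len(n_mito))
  if (n_ribo > 0) syms[n_mito + seq_len(n_ribo)] <- paste0("RPS", seq_len(n_ribo))
  count_matrix(v, gene_ids = sprintf("ID%05d", seq_len(n_genes)),
               gene_symbols = syms,
               barcodes = sprintf("CELL%03d", seq_along(cols)))
}

# QC fixture cell: 1 mito gene (index 1), 1 ribo gene (index 51), and
# (k_detect - 2) plain genes of count 1 starting at gene 101.
qc_cell <- function(k_detect, mito_umis, ribo_umis) {
  list(i = c(1L, 51L, 100L + seq_len(k_detect - 2)),
       x = c(mito_umis, ribo_umis, rep(1, k_detect - 2)))
}
anchor_cell <- function(n_genes) list(i = seq_len(n_genes), x = rep(1, n_genes))

# Wrap an already-normalized dense matrix as a normalized_matrix object.
nm_from_dense <- function(mat, gene_ids = NULL, barcodes = NULL,
                          gene_symbols = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(gene_symbols)) gene_symbols <- gene_ids
  if (is.null(barcodes)) barcodes <- sprintf("c%03d", seq_len(ncol(mat)))
  v <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  rownames(v) <- gene_ids
  colnames(v) <- barcodes
  structure(list(values = v, gene_ids = gene_ids,
                 gene_symbols = gene_symbols, barcodes = barcodes),
            class = "normalized_matrix")
}

# Independent full-enumeration two-sided rank-sum oracle (no ties):
# fraction of the C(N, nx) label assignments whose rank sum deviates from
# its mean by at least the observed deviation.
enum_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  N <- length(r)
  mu <- nx * (N + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(N, nx)
  W <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

# Adjusted Rand index (independent closed form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Stack the two clouds from embed_shifted_gaussians into one embedding
# plus barcode sets.
stack_groups <- function(g) {
  list(emb = embedding(rbind(g$case, g$control)),
       case = rownames(g$case),
       control = rownames(g$control))
}
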