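#' Construct a UMI count matrix
#'
#' The raw substrate of the pipeline: a sparse genes x cells matrix of
#' non-negative integer UMI counts together with gene identifiers, gene
#' symbols and cell barcodes. Orientation is fixed as genes x cells,
#' matching the 10x MatrixMarket layout on disk.
#'
#' @param values sparse (or dense) genes x cells matrix of UMI counts.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_symbols character vector of gene symbols (may repeat);
#'   defaults to `gene_ids`.
#' @param barcodes character vector of unique cell barcodes (columns).
#' @return An object of class `count_matrix` with fields `values`,
#'   `gene_ids`, `gene_symbols`, `barcodes`.
#' @export
count_matrix <- function(values, gene_ids, gene_symbols = gene_ids, barcodes) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  m <- structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         gene_symbols = as.character(gene_symbols),
         barcodes = as.character(barcodes)),
    class = "count_matrix")
  validate_count_matrix(m)
  rownames(m$values) <- m$gene_ids
  colnames(m$values) <- m$barcodes
  m
}

validate_count_matrix <- function(m) {
  if (!inherits(m, "count_matrix")) stop_validation("not a count_matrix")
  v <- m$values
  if (length(m$gene_ids) != nrow(v))
    stop_validation("length(gene_ids) must equal number of rows")
  if (length(m$gene_symbols) != nrow(v))
    stop_validation("length(gene_symbols) must equal number of rows")
  if (length(m$barcodes) != ncol(v))
    stop_validation("length(barcodes) must equal number of columns")
  if (anyDuplicated(m$gene_ids)) stop_validation("gene_ids must be unique")
  if (anyDuplicated(m$barcodes)) stop_validation("barcodes must be unique")
  x <- v@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop_validation("count values must be non-negative integers")
  invisible(m)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d stored non-zeros\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# Subset keeping metadata in sync; indices are logical or integer.
cm_subset <- function(m, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(m$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$values)) else cells
  count_matrix(m$values[gi, ci, drop = FALSE],
               gene_ids = m$gene_ids[gi],
               gene_symbols = m$gene_symbols[gi],
               barcodes = m$barcodes[ci])
}

find_10x_file <- function(directory, stems) {
  for (stem in stems) {
    for (p in file.path(directory, paste0(stem, c("", ".gz")))) {
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}

read_tsv_plain <- function(path, n_cols_min = 1) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", colClasses = "character",
                    blank.lines.skip = FALSE)
}

#' Read a 10x-style MatrixMarket count directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped (detected by suffix). The features file may have
#' 1, 2 or 3 columns (id / id+symbol / id+symbol+type); when symbols are
#' absent they default to the ids. Row/column order is preserved exactly.
#'
#' @param directory path containing the three files.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(directory) {
  if (!dir.exists(directory))
    stop_format(sprintf("directory not found: %s", directory))
  mtx <- find_10x_file(directory, "matrix.mtx")
  feat <- find_10x_file(directory, c("features.tsv", "genes.tsv"))
  bcs <- find_10x_file(directory, "barcodes.tsv")
  if (is.na(mtx)) stop_format(sprintf("missing matrix.mtx[.gz] in %s", directory))
  if (is.na(feat)) stop_format(sprintf("missing features.tsv[.gz]/genes.tsv[.gz] in %s", directory))
  if (is.na(bcs)) stop_format(sprintf("missing barcodes.tsv[.gz] in %s", directory))

  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else file(mtx)
  vals <- Matrix::readMM(con)
  features <- read_tsv_plain(feat)
  barcodes <- read_tsv_plain(bcs)[[1]]

  if (nrow(features) != nrow(vals))
    stop_integrity(sprintf(
      "features file has %d rows but matrix header declares %d genes",
      nrow(features), nrow(vals)))
  if (length(barcodes) != ncol(vals))
    stop_integrity(sprintf(
      "barcodes file has %d lines but matrix header declares %d cells",
      length(barcodes), ncol(vals)))

  gene_ids <- features[[1]]
  gene_symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  count_matrix(vals, gene_ids = gene_ids, gene_symbols = gene_symbols,
               barcodes = barcodes)
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Writes `matrix.mtx`, `features.tsv` (id, symbol) and `barcodes.tsv` so
#' that [read_counts_mtx()] reproduces the object exactly (values,
#' identifiers, order).
#'
#' @param m a [count_matrix()].
#' @param directory output directory (created if needed).
#' @export
write_counts_mtx <- function(m, directory) {
  validate_count_matrix(m)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    scshift_stop(sprintf("cannot create directory %s", directory), "scshift_io_error")
  Matrix::writeMM(m$values, file.path(directory, "matrix.mtx"))
  utils::write.table(
    data.frame(id = m$gene_ids, symbol = m$gene_symbols),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Read a per-cell annotation table
#'
#' Delimited text (tab or comma, auto-detected) with a header naming the
#' barcode, sample, condition and cluster columns. Condition must take the
#' values `case` / `control`. Extra columns are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `barcode`, `sample_id`, `condition`,
#'   `cluster`.
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (!length(hit))
      stop_format(sprintf("annotation is missing a column named one of: %s",
                          paste(cands, collapse = ", ")))
    df[[hit[1]]]
  }
  ann <- data.frame(
    barcode = as.character(pick(c("barcode", "cell", "cell_id"))),
    sample_id = as.character(pick(c("sample_id", "sample"))),
    condition = as.character(pick("condition")),
    cluster = as.character(pick(c("cluster", "cell_type", "celltype"))),
    stringsAsFactors = FALSE)
  validate_cell_annotation(ann)
  ann
}

validate_cell_annotation <- function(ann) {
  if (anyDuplicated(ann$barcode)) {
    dup <- ann$barcode[duplicated(ann$barcode)][1]
    stop_integrity(sprintf("duplicate barcode in annotation: %s", dup))
  }
  bad <- setdiff(unique(ann$condition), c("case", "control"))
  if (length(bad))
    stop_validation(sprintf(
      "condition must be 'case' or 'control'; found: %s",
      paste(bad, collapse = ", ")))
  invisible(ann)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description is
#' discarded; genes repeated within a set are deduplicated preserving order.
#'
#' @param path file path (plain or gzipped).
#' @return named list mapping set names to character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop_format(sprintf("GMT line %d has %d fields; need name, description and >= 1 gene",
                          i, length(fields)))
    nms[i] <- fields[1]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    dup <- nms[duplicated(nms)][1]
    stop_integrity(sprintf("duplicate gene-set name: %s", dup))
  }
  names(sets) <- nms
  sets
}
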