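#' Quality-control thresholds
#'
#' Defaults are the study values: genes kept when expressed in at least 3
#' cells; cells kept with at least 200 detected genes at object creation,
#' then excluded when detected genes fall below 500 or above 3500, or when
#' more than 7% of UMIs map to mitochondrial or ribosomal genes.
#'
#' @param min_cells_per_gene keep genes expressed (count > 0) in at least
#'   this many cells.
#' @param min_genes_loose initial minimum detected genes per cell.
#' @param min_genes,max_genes detected-gene bounds for the low-quality cell
#'   exclusion (cells with counts strictly below `min_genes` or strictly
#'   above `max_genes` are dropped).
#' @param organelle_max maximum tolerated organelle UMI fraction (strictly
#'   greater is dropped).
#' @param organelle_rule `"either"` drops a cell when the mitochondrial OR
#'   the ribosomal fraction alone exceeds `organelle_max` (literal reading);
#'   `"combined"` compares their sum against the threshold.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L,
                          min_genes_loose = 200L,
                          min_genes = 500L,
                          max_genes = 3500L,
                          organelle_max = 0.07,
                          organelle_rule = c("either", "combined")) {
  organelle_rule <- match.arg(organelle_rule)
  if (!(min_genes_loose <= min_genes && min_genes < max_genes))
    stop_validation("need min_genes_loose <= min_genes < max_genes")
  if (!(organelle_max > 0 && organelle_max < 1))
    stop_validation("organelle_max must be in (0, 1)")
  if (min_cells_per_gene < 0) stop_validation("min_cells_per_gene must be >= 0")
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_loose = as.integer(min_genes_loose),
                 min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 organelle_max = organelle_max,
                 organelle_rule = organelle_rule),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Detected genes, total UMIs, and the fractions of UMIs mapping to
#' mitochondrial and ribosomal genes, identified by gene-symbol prefix.
#' Cells with zero total UMIs get fractions of 0.
#'
#' @param m a [count_matrix()].
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param ribo_prefixes gene-symbol prefixes marking ribosomal genes.
#' @return data.frame with one row per cell: `barcode`, `n_genes_detected`,
#'   `n_umis`, `mito_fraction`, `ribo_fraction`.
#' @export
compute_qc_metrics <- function(m, mito_prefix = "MT-",
                               ribo_prefixes = c("RPS", "RPL")) {
  validate_count_matrix(m)
  v <- m$values
  n_umis <- Matrix::colSums(v)
  n_genes <- Matrix::colSums(v > 0)
  is_mito <- startsWith(m$gene_symbols, mito_prefix)
  is_ribo <- Reduce(`|`, lapply(ribo_prefixes, function(p)
    startsWith(m$gene_symbols, p)))
  sum_rows <- function(sel) {
    if (!any(sel)) return(numeric(ncol(v)))
    Matrix::colSums(v[sel, , drop = FALSE])
  }
  safe_frac <- function(x) ifelse(n_umis > 0, x / n_umis, 0)
  data.frame(barcode = m$barcodes,
             n_genes_detected = as.integer(n_genes),
             n_umis = n_umis,
             mito_fraction = safe_frac(sum_rows(is_mito)),
             ribo_fraction = safe_frac(sum_rows(is_ribo)),
             stringsAsFactors = FALSE)
}

#' Apply the quality-control filters
#'
#' Filter order is fixed: (1) drop genes expressed in fewer than
#' `min_cells_per_gene` cells; (2) drop cells with fewer than
#' `min_genes_loose` detected genes; (3) drop cells with detected genes
#' below `min_genes` or above `max_genes`; (4) drop cells whose organelle
#' (mitochondrial/ribosomal) UMI fraction exceeds `organelle_max`. All
#' cell metrics are recomputed on the gene-filtered matrix. Ordering of
#' surviving rows/columns is preserved.
#'
#' @param m a [count_matrix()].
#' @param thresholds a [qc_thresholds()] object.
#' @inheritParams compute_qc_metrics
#' @return list with `matrix` (filtered [count_matrix()]) and `report`
#'   (class `qc_report`: per-step removal counts, thresholds echo).
#' @export
apply_qc_filters <- function(m, thresholds = qc_thresholds(),
                             mito_prefix = "MT-",
                             ribo_prefixes = c("RPS", "RPL")) {
  validate_count_matrix(m)
  t <- thresholds
  steps <- list()
  n_genes0 <- nrow(m$values); n_cells0 <- ncol(m$values)

  # step 1: gene filter ("expressed in at least N cells" — boundary kept)
  cells_per_gene <- Matrix::rowSums(m$values > 0)
  keep_gene <- cells_per_gene >= t$min_cells_per_gene
  steps$gene_filter <- list(kind = "genes", removed = sum(!keep_gene),
                            retained = sum(keep_gene))
  m1 <- cm_subset(m, genes = which(keep_gene))
  if (nrow(m1$values) == 0)
    stop_validation("QC step 'gene_filter' removed all genes")

  qc <- compute_qc_metrics(m1, mito_prefix, ribo_prefixes)

  drop_cells <- function(mcur, qccur, keep, step_name) {
    steps[[step_name]] <<- list(kind = "cells", removed = sum(!keep),
                                retained = sum(keep))
    if (!any(keep))
      stop_validation(sprintf("QC step '%s' removed all cells", step_name))
    list(m = cm_subset(mcur, cells = which(keep)),
         qc = qccur[keep, , drop = FALSE])
  }

  # step 2: loose minimum detected genes
  r <- drop_cells(m1, qc, qc$n_genes_detected >= t$min_genes_loose,
                  "min_genes_loose")
  # step 3: detected-gene window (strictly outside [min_genes, max_genes])
  r <- drop_cells(r$m, r$qc,
                  r$qc$n_genes_detected >= t$min_genes &
                    r$qc$n_genes_detected <= t$max_genes,
                  "gene_window")
  # step 4: organelle fraction (strictly above threshold is dropped)
  organelle_fail <- if (t$organelle_rule == "either") {
    r$qc$mito_fraction > t$organelle_max | r$qc$ribo_fraction > t$organelle_max
  } else {
    (r$qc$mito_fraction + r$qc$ribo_fraction) > t$organelle_max
  }
  r <- drop_cells(r$m, r$qc, !organelle_fail, "organelle_fraction")

  report <- structure(list(
    input = list(genes = n_genes0, cells = n_cells0),
    output = list(genes = nrow(r$m$values), cells = ncol(r$m$values)),
    steps = steps,
    thresholds = unclass(t)), class = "qc_report")
  list(matrix = r$m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d genes x %d cells -> %d genes x %d cells\n",
              x$input$genes, x$input$cells, x$output$genes, x$output$cells))
  for (nm in names(x$steps))
    cat(sprintf("  %-18s removed %d %s\n", nm, x$steps[[nm]]$removed,
                x$steps[[nm]]$kind))
  invisible(x)
}
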