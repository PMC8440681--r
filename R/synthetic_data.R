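#' Specification for the synthetic scRNA-seq generator
#'
#' Describes a PBMC-like two-condition experiment at desk scale: a handful
#' of clusters with negative-binomial UMI noise, cluster marker genes,
#' a condition-specific expression shift planted in one cluster,
#' mitochondrial/ribosomal ("organelle") genes with a controlled per-cell
#' UMI load, and a fraction of QC-failing outlier cells.
#'
#' @param n_genes total genes (organelle genes included).
#' @param n_cells_per_condition cells per condition (two samples each).
#' @param clusters data.frame with columns `name`, `proportion` (summing
#'   to 1) and `scale` (per-cluster library scale factor).
#' @param de_genes_per_cluster marker genes per cluster.
#' @param marker_fold linear fold of markers in their cluster (>= 1).
#' @param shift list: `cluster` (perturbed cluster name), `n_genes`,
#'   `fold` (linear, applied to case cells only, >= 1), `embedding_shift`
#'   (PC1-sd units; consumed by the embedding-level generator, not the
#'   count path).
#' @param dispersion negative-binomial size parameter.
#' @param library_size list `mean_log`, `sd_log` of the log-normal total
#'   UMI depth per cell.
#' @param organelle list: `gene_fraction` of genes flagged "MT-"/"RPS",
#'   `load_mean`, `load_sd` of the per-cell organelle UMI share.
#' @param outlier_fraction fraction of cells made to fail QC (high
#'   organelle load or too few detected genes).
#' @param seed integer seed; same seed gives byte-identical outputs.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           n_cells_per_condition = 1000L,
                           clusters = data.frame(
                             name = c("A", "B", "C"),
                             proportion = c(0.5, 0.3, 0.2),
                             scale = c(1, 1, 1),
                             stringsAsFactors = FALSE),
                           de_genes_per_cluster = 30L,
                           marker_fold = 4,
                           shift = list(cluster = "A", n_genes = 30L,
                                        fold = 3, embedding_shift = 0),
                           dispersion = 2,
                           library_size = list(mean_log = log(3000),
                                               sd_log = 0.2),
                           organelle = list(gene_fraction = 0.05,
                                            load_mean = 0.03,
                                            load_sd = 0.01),
                           outlier_fraction = 0.05,
                           seed = 1L) {
  if (abs(sum(clusters$proportion) - 1) > 1e-8)
    stop_validation("cluster proportions must sum to 1")
  if (is.null(clusters$scale)) clusters$scale <- 1
  if (marker_fold < 1 || shift$fold < 1)
    stop_validation("all folds must be >= 1")
  if (shift$embedding_shift < 0)
    stop_validation("embedding_shift must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction > 1 ||
      organelle$gene_fraction < 0 || organelle$gene_fraction > 1)
    stop_validation("fractions must be in [0, 1]")
  if (!shift$cluster %in% clusters$name)
    stop_validation("shift$cluster must be one of the cluster names")
  if (dispersion <= 0) stop_validation("dispersion must be > 0")
  n_org <- round(organelle$gene_fraction * n_genes)
  needed <- de_genes_per_cluster * nrow(clusters) + shift$n_genes
  if (needed > n_genes - n_org)
    stop_validation(sprintf(
      "infeasible spec: %d marker+shift genes requested but only %d non-organelle genes",
      needed, n_genes - n_org))
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_condition = as.integer(n_cells_per_condition),
                 clusters = clusters,
                 de_genes_per_cluster = as.integer(de_genes_per_cluster),
                 marker_fold = marker_fold,
                 shift = shift,
                 dispersion = dispersion,
                 library_size = library_size,
                 organelle = organelle,
                 outlier_fraction = outlier_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-condition UMI dataset
#'
#' Counts are drawn gene-by-cell from a negative binomial with
#' `mean = baseline weight x marker fold x condition-shift fold x cell
#' depth share` and `size = dispersion`. Within each cell, non-organelle
#' gene means are scaled to `(1 - load) x depth` and organelle gene means
#' to `load x depth`, so the expected organelle UMI fraction equals the
#' drawn per-cell load. Outlier cells (at `outlier_fraction`) are given
#' either an organelle load above the QC threshold or a depth low enough
#' to fail the detected-gene minimum. Fully reproducible from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `matrix` ([count_matrix()]), `annotation` (barcode,
#'   sample_id, condition, cluster), `truth` (list `cells`, `genes` of
#'   ground-truth tables), `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop_validation("spec must be a synthetic_spec")
  set.seed(spec$seed)
  nG <- spec$n_genes
  nC <- 2L * spec$n_cells_per_condition

  # gene universe: organelle genes first (half MT-, half RPS), then G-genes
  n_org <- round(spec$organelle$gene_fraction * nG)
  n_mt <- n_org %/% 2
  symbols <- c(if (n_mt > 0) paste0("MT-", seq_len(n_mt)),
               if (n_org - n_mt > 0) paste0("RPS", seq_len(n_org - n_mt)),
               sprintf("G%06d", seq_len(nG - n_org)))
  gene_ids <- symbols
  is_org <- seq_len(nG) <= n_org

  # baseline relative abundances
  w <- stats::rgamma(nG, shape = 2, rate = 1)

  # markers and shift genes: deterministic blocks among non-organelle genes
  nonorg <- which(!is_org)
  marker_of <- rep(NA_character_, nG)
  kcl <- nrow(spec$clusters)
  pos <- 0L
  for (k in seq_len(kcl)) {
    idx <- nonorg[pos + seq_len(spec$de_genes_per_cluster)]
    marker_of[idx] <- spec$clusters$name[k]
    pos <- pos + spec$de_genes_per_cluster
  }
  shift_idx <- nonorg[pos + seq_len(spec$shift$n_genes)]
  shifted_in <- rep(NA_character_, nG)
  shifted_in[shift_idx] <- spec$shift$cluster

  # cells
  condition <- rep(c("case", "control"), each = spec$n_cells_per_condition)
  sample_id <- paste0(condition, "_", rep(rep(1:2, length.out = spec$n_cells_per_condition), 2))
  cluster <- c(sample(spec$clusters$name, spec$n_cells_per_condition,
                      replace = TRUE, prob = spec$clusters$proportion),
               sample(spec$clusters$name, spec$n_cells_per_condition,
                      replace = TRUE, prob = spec$clusters$proportion))
  barcodes <- sprintf("CELL%06d", seq_len(nC))

  depth <- stats::rlnorm(nC, spec$library_size$mean_log, spec$library_size$sd_log) *
    spec$clusters$scale[match(cluster, spec$clusters$name)]
  load <- stats::rnorm(nC, spec$organelle$load_mean, spec$organelle$load_sd)
  load <- pmin(pmax(load, 0), 1)

  is_outlier <- stats::runif(nC) < spec$outlier_fraction
  outlier_type <- rep("none", nC)
  if (any(is_outlier)) {
    kind <- sample(c("organelle", "low_depth"), sum(is_outlier), replace = TRUE)
    outlier_type[is_outlier] <- kind
    load[is_outlier][kind == "organelle"] <-
      stats::runif(sum(kind == "organelle"), 0.09, 0.25)
    depth[is_outlier][kind == "low_depth"] <-
      stats::runif(sum(kind == "low_depth"), 150, 400)
  }

  # per-cluster fold profiles on non-organelle genes
  fold_profile <- matrix(1, nG, kcl, dimnames = list(NULL, spec$clusters$name))
  for (k in seq_len(kcl))
    fold_profile[which(marker_of == spec$clusters$name[k]), k] <- spec$marker_fold

  w_org <- w[is_org]
  triplets_i <- vector("list", nC)
  triplets_x <- vector("list", nC)
  for (c_i in seq_len(nC)) {
    wf <- w * fold_profile[, cluster[c_i]]
    if (condition[c_i] == "case" && cluster[c_i] == spec$shift$cluster)
      wf[shift_idx] <- wf[shift_idx] * spec$shift$fold
    mu <- numeric(nG)
    wo <- wf[!is_org]
    mu[!is_org] <- wo / sum(wo) * (1 - load[c_i]) * depth[c_i]
    if (n_org > 0)
      mu[is_org] <- w_org / sum(w_org) * load[c_i] * depth[c_i]
    cnt <- stats::rnbinom(nG, mu = mu, size = spec$dispersion)
    nz <- which(cnt > 0)
    triplets_i[[c_i]] <- nz
    triplets_x[[c_i]] <- cnt[nz]
  }
  nnz <- lengths(triplets_i)
  values <- Matrix::sparseMatrix(
    i = unlist(triplets_i),
    j = rep.int(seq_len(nC), nnz),
    x = unlist(triplets_x),
    dims = c(nG, nC))

  m <- count_matrix(values, gene_ids = gene_ids, gene_symbols = symbols,
                    barcodes = barcodes)
  ann <- data.frame(barcode = barcodes, sample_id = sample_id,
                    condition = condition, cluster = cluster,
                    stringsAsFactors = FALSE)
  truth <- list(
    cells = data.frame(barcode = barcodes, cluster = cluster,
                       condition = condition, sample_id = sample_id,
                       outlier_type = outlier_type,
                       qc_expected_pass = !is_outlier,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_ids, symbol = symbols,
                       organelle = is_org,
                       marker_of = marker_of, shifted_in = shifted_in,
                       stringsAsFactors = FALSE))
  list(matrix = m, annotation = ann, truth = truth, spec = spec)
}

#' Embedding-level generator: two Gaussian clouds with a planted shift
#'
#' Both groups are standard Gaussian in K dimensions; the case group's
#' first coordinate is mean-shifted by `delta`. Used to test the distance
#' statistic in isolation: the theoretical Bhattacharyya distance between
#' the generating distributions is `delta^2 / 8`.
#'
#' @param n_per_group cells per group (must exceed K).
#' @param K embedding dimension.
#' @param delta mean shift of the case group's first coordinate, in sd
#'   units.
#' @param seed integer seed.
#' @return list `case`, `control`: n x K matrices with barcode rownames.
#' @export
embed_shifted_gaussians <- function(n_per_group, K, delta, seed = 1L) {
  if (n_per_group < K + 1)
    stop_validation("n_per_group must be at least K + 1")
  set.seed(seed)
  control <- matrix(stats::rnorm(n_per_group * K), n_per_group, K)
  case <- matrix(stats::rnorm(n_per_group * K), n_per_group, K)
  case[, 1] <- case[, 1] + delta
  rownames(control) <- sprintf("ctrl_%06d", seq_len(n_per_group))
  rownames(case) <- sprintf("case_%06d", seq_len(n_per_group))
  list(case = case, control = control)
}
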