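#' Fit a Gaussian summary to a point cloud
#'
#' Mean and sample covariance (n-1 denominator) of an n x K coordinate
#' matrix, with a ridge `eps * (trace/K) * I` added to the covariance for
#' numerical stability. When the raw covariance has zero trace (all points
#' identical) the ridge scale falls back to 1 so the summary stays usable.
#'
#' @param points numeric n x K matrix, n >= 2.
#' @param ridge_eps ridge multiplier (default 1e-6).
#' @param diagonal keep only the covariance diagonal (independent-axes
#'   model); default FALSE (full covariance).
#' @return object of class `gaussian_summary`: `mean`, `covariance`, `n`.
#' @export
gaussian_summary <- function(points, ridge_eps = 1e-6, diagonal = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop_validation("gaussian_summary needs at least 2 points")
  K <- ncol(points)
  S <- stats::cov(points)
  if (diagonal) S <- diag(diag(S), K)
  s <- sum(diag(S)) / K
  if (!is.finite(s) || s <= 0) s <- 1
  structure(list(mean = colMeans(points),
                 covariance = S + ridge_eps * s * diag(K),
                 n = n),
            class = "gaussian_summary")
}

#' Build a Gaussian summary from explicit moments
#'
#' Used for analytic test cases and externally specified distributions;
#' no ridge is added.
#'
#' @param mean length-K mean vector.
#' @param covariance K x K symmetric positive-definite matrix.
#' @param n nominal sample size (default Inf).
#' @return object of class `gaussian_summary`.
#' @export
gaussian_from_moments <- function(mean, covariance, n = Inf) {
  covariance <- as.matrix(covariance)
  if (length(mean) != nrow(covariance) || nrow(covariance) != ncol(covariance))
    stop_validation("mean / covariance dimensions disagree")
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop_validation("covariance must be symmetric (within 1e-10)")
  structure(list(mean = as.numeric(mean), covariance = covariance, n = n),
            class = "gaussian_summary")
}

chol_or_fail <- function(S, what) {
  tryCatch(chol(S), error = function(e)
    stop_numerical(sprintf(
      "%s is numerically singular (condition number ~ %.3g)", what, kappa(S))))
}

#' Bhattacharyya distance between two Gaussians
#'
#' Closed form for multivariate normals:
#' `D_B = (1/8) (mu_a - mu_b)' Sbar^-1 (mu_a - mu_b)
#'        + (1/2) ln( det Sbar / sqrt(det Sa * det Sb) )`,
#' with `Sbar = (Sa + Sb)/2`. Determinants are computed in log space via
#' Cholesky factors; the result is clamped at 0 against roundoff.
#'
#' @param a,b `gaussian_summary` objects of equal dimension.
#' @return non-negative finite scalar.
#' @export
bhattacharyya_gaussian <- function(a, b) {
  if (length(a$mean) != length(b$mean))
    stop_validation("summaries have different dimensions")
  Sbar <- (a$covariance + b$covariance) / 2
  ch_bar <- chol_or_fail(Sbar, "mean covariance (Sa+Sb)/2")
  ch_a <- chol_or_fail(a$covariance, "covariance of first summary")
  ch_b <- chol_or_fail(b$covariance, "covariance of second summary")
  logdet <- function(ch) 2 * sum(log(diag(ch)))
  d <- a$mean - b$mean
  q <- backsolve(ch_bar, d, transpose = TRUE)
  D <- sum(q^2) / 8 +
    0.5 * (logdet(ch_bar) - 0.5 * (logdet(ch_a) + logdet(ch_b)))
  if (!is.finite(D)) stop_numerical("Bhattacharyya distance is not finite")
  max(D, 0)
}

#' Subsampling scheme for the shift statistic
#'
#' Defaults follow the study: 500 cells per draw, 100 replicates, and
#' cell types only scored when each condition group has at least 500 cells.
#'
#' @param n_sub cells per subsample draw.
#' @param n_reps number of replicates.
#' @param min_cluster_size minimum group size for a cell type to be scored.
#' @param seed root seed; every draw derives its own stream from it.
#' @param cov_mode `"full"` (default) or `"diagonal"` covariance for the
#'   fitted Gaussians.
#' @return object of class `subsample_scheme`.
#' @export
subsample_scheme <- function(n_sub = 500L, n_reps = 100L,
                             min_cluster_size = 500L, seed = 1L,
                             cov_mode = c("full", "diagonal")) {
  cov_mode <- match.arg(cov_mode)
  if (n_reps < 2) stop_validation("n_reps must be >= 2")
  if (n_sub < 2) stop_validation("n_sub must be >= 2")
  structure(list(n_sub = as.integer(n_sub), n_reps = as.integer(n_reps),
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed), cov_mode = cov_mode),
            class = "subsample_scheme")
}

# Deterministic seed stream derived from (root seed, string key); stays
# below 2^31 so set.seed() accepts it. Adding new keys (e.g. more cell
# types) never perturbs existing streams.
derive_seed <- function(root, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(root)) * 48271 + h) %% 2147483647)
}

emb_coords <- function(emb) {
  if (inherits(emb, "sc_embedding")) emb$coords else as.matrix(emb)
}

resolve_barcodes <- function(coords, barcodes, what) {
  idx <- match(barcodes, rownames(coords))
  if (anyNA(idx))
    stop_validation(sprintf("%s barcodes absent from embedding: %s", what,
                            paste(utils::head(barcodes[is.na(idx)], 3), collapse = ", ")))
  idx
}

#' Observed between-condition distances
#'
#' For each replicate, draw `n_sub` cells without replacement independently
#' from the case and the control group, fit Gaussian summaries in the
#' embedding, and return the Bhattacharyya distance. Fully reproducible
#' from the scheme's seed; draws use per-(label, role, replicate) derived
#' streams.
#'
#' @param emb an `sc_embedding` (or a coordinate matrix with barcode
#'   rownames).
#' @param cells_case,cells_control barcode vectors of the two groups.
#' @param scheme a [subsample_scheme()].
#' @param label stream label (use the cell-type name so results are stable
#'   when other cell types are added).
#' @return numeric vector of length `n_reps`.
#' @export
observed_distances <- function(emb, cells_case, cells_control,
                               scheme = subsample_scheme(), label = "group") {
  coords <- emb_coords(emb)
  ic <- resolve_barcodes(coords, cells_case, "case")
  ik <- resolve_barcodes(coords, cells_control, "control")
  for (nm in c("case", "control")) {
    n <- if (nm == "case") length(ic) else length(ik)
    if (n < scheme$min_cluster_size)
      stop_skip(sprintf("%s group has %d cells, below min_cluster_size = %d",
                        nm, n, scheme$min_cluster_size))
    if (n < scheme$n_sub)
      stop_skip(sprintf("%s group has %d cells, fewer than n_sub = %d",
                        nm, n, scheme$n_sub))
  }
  diag_cov <- identical(scheme$cov_mode, "diagonal")
  vapply(seq_len(scheme$n_reps), function(r) {
    set.seed(derive_seed(scheme$seed, paste(label, "observed", r, sep = "/")))
    i <- sample(ic, scheme$n_sub)
    j <- sample(ik, scheme$n_sub)
    bhattacharyya_gaussian(
      gaussian_summary(coords[i, , drop = FALSE], diagonal = diag_cov),
      gaussian_summary(coords[j, , drop = FALSE], diagonal = diag_cov))
  }, numeric(1))
}

#' Mixed-pool null distances
#'
#' For each replicate, pool both groups, split the pool at random into two
#' halves, and draw one `n_sub`-cell sample without replacement from each
#' half; the two draws are therefore disjoint. Splitting before
#' subsampling reproduces the two-stage sampling of
#' [observed_distances()] exactly under label exchangeability, so the
#' null is calibrated: drawing both disjoint samples directly from the
#' pool instead would give the null a weaker finite-population correction
#' than the observed draws and bias the fold change slightly below 1.
#'
#' @inheritParams observed_distances
#' @return numeric vector of length `n_reps`.
#' @export
null_distances <- function(emb, cells_case, cells_control,
                           scheme = subsample_scheme(), label = "group") {
  coords <- emb_coords(emb)
  # sorted so the draw is exactly invariant to swapping the group labels
  pool <- sort(c(resolve_barcodes(coords, cells_case, "case"),
                 resolve_barcodes(coords, cells_control, "control")))
  if (length(pool) < 2 * scheme$n_sub)
    stop_skip(sprintf("pooled group has %d cells, fewer than 2 * n_sub = %d",
                      length(pool), 2 * scheme$n_sub))
  n_half <- length(pool) %/% 2
  diag_cov <- identical(scheme$cov_mode, "diagonal")
  vapply(seq_len(scheme$n_reps), function(r) {
    set.seed(derive_seed(scheme$seed, paste(label, "null", r, sep = "/")))
    perm <- sample(pool)
    a <- sample(perm[seq_len(n_half)], scheme$n_sub)
    b <- sample(perm[(n_half + 1):length(pool)], scheme$n_sub)
    bhattacharyya_gaussian(
      gaussian_summary(coords[a, , drop = FALSE], diagonal = diag_cov),
      gaussian_summary(coords[b, , drop = FALSE], diagonal = diag_cov))
  }, numeric(1))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact (via the rank-sum distribution) when the smaller group has at most
#' `exact_max_n` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric vectors.
#' @param exact_max_n maximum smaller-group size for the exact branch.
#' @return p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 10L) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop_validation("both samples must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- anyDuplicated(z) > 0
  if (!ties && min(nx, ny) <= exact_max_n) {
    p <- if (U > mu) 2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
         else 2 * stats::pwilcox(U, nx, ny)
    return(min(1, p))
  }
  N <- nx + ny
  tab <- table(z)
  sig2 <- nx * ny / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
  if (sig2 <= 0) return(1)  # all observations tied
  zstat <- max(0, abs(U - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-zstat))
}

#' Shift statistic from observed and null distance replicates
#'
#' Fold change is the mean observed distance divided by the mean null
#' distance (so it equals the mean of the normalized observed distances);
#' the p-value is a two-sided Wilcoxon rank-sum test of observed versus
#' null replicates.
#'
#' @param observed,null numeric distance vectors from
#'   [observed_distances()] / [null_distances()].
#' @param cell_type label carried into the result.
#' @return object of class `shift_result`: `cell_type`, `observed`, `null`,
#'   `normalized_observed`, `fold_change`, `p_value`.
#' @export
shift_statistic <- function(observed, null, cell_type = "group") {
  if (!length(observed) || !length(null))
    stop_validation("observed and null must be non-empty")
  mnull <- mean(null)
  if (mnull == 0) stop_validation("degenerate null: mean(null) = 0")
  structure(list(cell_type = cell_type,
                 observed = observed,
                 null = null,
                 normalized_observed = observed / mnull,
                 fold_change = mean(observed) / mnull,
                 p_value = wilcoxon_rank_sum(observed, null)),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("shift_result [%s]: fold_change = %.3f, p = %.3g (%d obs / %d null reps)\n",
              x$cell_type, x$fold_change, x$p_value,
              length(x$observed), length(x$null)))
  invisible(x)
}

#' Shift statistic for every cell type
#'
#' Runs [observed_distances()], [null_distances()] and [shift_statistic()]
#' per cluster label, using the cluster name as the random-stream label.
#' Cell types whose case or control group is below `min_cluster_size` are
#' reported as skipped with the reason, mirroring the study's inclusion
#' rule (lineages with enough cells in each condition).
#'
#' @param emb an `sc_embedding` (or coordinate matrix).
#' @param ann annotation data.frame (barcode, condition, cluster).
#' @param scheme a [subsample_scheme()].
#' @param clusters optional subset of cluster labels to score.
#' @return list with `results` (named list of `shift_result`) and `table`
#'   (one row per cluster: sizes, fold_change, p_value, skipped, reason).
#' @export
shift_per_celltype <- function(emb, ann, scheme = subsample_scheme(),
                               clusters = NULL) {
  validate_cell_annotation(ann)
  coords <- emb_coords(emb)
  ann <- ann[ann$barcode %in% rownames(coords), , drop = FALSE]
  if (is.null(clusters)) clusters <- sort(unique(ann$cluster))
  results <- list()
  rows <- lapply(clusters, function(ct) {
    case <- ann$barcode[ann$cluster == ct & ann$condition == "case"]
    ctrl <- ann$barcode[ann$cluster == ct & ann$condition == "control"]
    res <- tryCatch({
      obs <- observed_distances(emb, case, ctrl, scheme, label = ct)
      nul <- null_distances(emb, case, ctrl, scheme, label = ct)
      shift_statistic(obs, nul, cell_type = ct)
    }, scshift_skip_error = function(e) e)
    if (inherits(res, "shift_result")) {
      results[[ct]] <<- res
      data.frame(cell_type = ct, n_case = length(case), n_control = length(ctrl),
                 fold_change = res$fold_change, p_value = res$p_value,
                 n_obs_reps = length(res$observed), n_null_reps = length(res$null),
                 skipped = FALSE, reason = "", stringsAsFactors = FALSE)
    } else {
      data.frame(cell_type = ct, n_case = length(case), n_control = length(ctrl),
                 fold_change = NA_real_, p_value = NA_real_,
                 n_obs_reps = 0L, n_null_reps = 0L,
                 skipped = TRUE, reason = conditionMessage(res),
                 stringsAsFactors = FALSE)
    }
  })
  list(results = results, table = do.call(rbind, rows))
}

#' Long-format replicate table for a set of shift results
#'
#' One row per (cell type, replicate, kind) with kind in
#' observed / null / normalized — the three bar groups of the study's
#' distance figure.
#'
#' @param results named list of `shift_result` objects.
#' @return data.frame with columns `cell_type`, `kind`, `replicate`,
#'   `distance`.
#' @export
shift_replicate_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      cell_type = r$cell_type,
      kind = rep(c("observed", "null", "normalized"),
                 times = c(length(r$observed), length(r$null),
                           length(r$normalized_observed))),
      replicate = c(seq_along(r$observed), seq_along(r$null),
                    seq_along(r$normalized_observed)),
      distance = c(r$observed, r$null, r$normalized_observed),
      stringsAsFactors = FALSE)
  }))
}
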