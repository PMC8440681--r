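test_that("gaussian_summary matches hand computation and is permutation-invariant", {
  g <- gaussian_summary(rbind(c(0, 0), c(2, 0)))
  expect_equal(g$mean, c(1, 0))
  # raw covariance diag(2, 0); ridge = 1e-6 * (trace/K = 1) * I
  expect_equal(g$covariance, diag(c(2 + 1e-6, 1e-6)), tolerance = 1e-15)
  expect_equal(g$n, 2)
  # identical points: covariance is the ridge only
  gi <- gaussian_summary(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(gi$covariance, 1e-6 * diag(2), tolerance = 1e-18)
  # permuting rows changes nothing
  set.seed(1)
  pts <- matrix(rnorm(40), 10, 4)
  expect_equal(gaussian_summary(pts), gaussian_summary(pts[sample(10), ]))
  expect_error(gaussian_summary(pts[1, , drop = FALSE]),
               class = "scshift_validation_error")
})

test_that("Bhattacharyya distance reproduces closed-form 1-D cases", {
  n01 <- gaussian_from_moments(0, matrix(1))
  n21 <- gaussian_from_moments(2, matrix(1))
  n04 <- gaussian_from_moments(0, matrix(4))
  expect_equal(bhattacharyya_gaussian(n01, n21), 0.5, tolerance = 1e-12)
  expect_equal(bhattacharyya_gaussian(n01, n04), 0.5 * log(1.25),
               tolerance = 1e-12)
  expect_equal(bhattacharyya_gaussian(n01, n01), 0, tolerance = 1e-12)
})

test_that("D_B is symmetric and invariant under a common rotation", {
  set.seed(3)
  for (rep in 1:5) {
    K <- 4
    a <- gaussian_summary(matrix(rnorm(60 * K), 60, K))
    b <- gaussian_summary(matrix(rnorm(60 * K, mean = 0.5), 60, K))
    d_ab <- bhattacharyya_gaussian(a, b)
    expect_equal(d_ab, bhattacharyya_gaussian(b, a), tolerance = 1e-12)
    Q <- qr.Q(qr(matrix(rnorm(K * K), K, K)))
    rot <- function(g) gaussian_from_moments(as.numeric(Q %*% g$mean),
                                             Q %*% g$covariance %*% t(Q))
    expect_equal(bhattacharyya_gaussian(rot(a), rot(b)), d_ab,
                 tolerance = 1e-8)
  }
})

test_that("singular mean covariance raises a numerical error naming the condition number", {
  a <- gaussian_from_moments(c(0, 0), matrix(0, 2, 2))
  expect_error(bhattacharyya_gaussian(a, a), "condition number",
               class = "scshift_numerical_error")
})

test_that("observed_distances separates a planted shift and is seed-deterministic", {
  sh <- stack_groups(embed_shifted_gaussians(800, 5, delta = 5, seed = 10))
  same <- stack_groups(embed_shifted_gaussians(800, 5, delta = 0, seed = 11))
  scheme <- subsample_scheme(n_sub = 200, n_reps = 20, min_cluster_size = 200,
                             seed = 99)
  d_shift <- observed_distances(sh$emb, sh$case, sh$control, scheme)
  d_same <- observed_distances(same$emb, same$case, same$control, scheme)
  # every shifted replicate exceeds every same-distribution replicate
  expect_gt(min(d_shift), max(d_same))
  expect_true(all(d_same >= 0))
  # identical call, identical seed -> identical vector
  expect_identical(d_shift,
                   observed_distances(sh$emb, sh$case, sh$control, scheme))
  # different seed -> different draws
  scheme2 <- subsample_scheme(200, 20, 200, seed = 100)
  expect_false(identical(d_shift,
                         observed_distances(sh$emb, sh$case, sh$control, scheme2)))
})

test_that("n_sub equal to the group size removes sampling variability", {
  g <- stack_groups(embed_shifted_gaussians(120, 3, delta = 1, seed = 5))
  scheme <- subsample_scheme(n_sub = 120, n_reps = 5, min_cluster_size = 100,
                             seed = 1)
  d <- observed_distances(g$emb, g$case, g$control, scheme)
  expect_equal(diff(range(d)), 0, tolerance = 1e-14)
})

test_that("group-size guards raise skip errors", {
  g <- stack_groups(embed_shifted_gaussians(100, 3, delta = 0, seed = 6))
  scheme <- subsample_scheme(n_sub = 50, n_reps = 5, min_cluster_size = 200,
                             seed = 1)
  expect_error(observed_distances(g$emb, g$case, g$control, scheme),
               "below min_cluster_size", class = "scshift_skip_error")
  scheme2 <- subsample_scheme(n_sub = 150, n_reps = 5, min_cluster_size = 10,
                              seed = 1)
  expect_error(null_distances(g$emb, g$case, g$control, scheme2),
               "2 \\* n_sub", class = "scshift_skip_error")
})

test_that("null distances are non-negative, deterministic and label-symmetric", {
  g <- stack_groups(embed_shifted_gaussians(400, 4, delta = 0, seed = 12))
  scheme <- subsample_scheme(n_sub = 100, n_reps = 25, min_cluster_size = 100,
                             seed = 3)
  nd <- null_distances(g$emb, g$case, g$control, scheme)
  expect_true(all(nd >= 0))
  expect_true(all(nd > 0))  # finite-sample bias keeps them positive
  expect_identical(nd, null_distances(g$emb, g$case, g$control, scheme))
  # pooling is exactly symmetric in the two labels
  expect_identical(nd, null_distances(g$emb, g$control, g$case, scheme))
})

test_that("shift_statistic normalization, fold change and rank-sum example", {
  nul <- c(1, 2, 3)
  r <- shift_statistic(c(5, 6, 7), nul)
  # exact enumeration over C(6,3)=20 assignments gives p = 2/20
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$p_value, enum_ranksum_p(c(5, 6, 7), nul), tolerance = 1e-12)
  expect_equal(r$fold_change, 6 / 2)
  expect_equal(r$fold_change, mean(r$normalized_observed))
  # observed = null -> fold 1, p 1
  ri <- shift_statistic(nul, nul)
  expect_equal(ri$fold_change, 1)
  expect_equal(ri$p_value, 1)
  # elementwise doubling -> fold exactly 2
  expect_equal(shift_statistic(2 * nul, nul)$fold_change, 2)
  expect_error(shift_statistic(c(1, 2), c(0, 0)),
               class = "scshift_validation_error")
})

test_that("wilcoxon_rank_sum: exact branch, ties, and approximation accuracy", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)  # tied -> approx
  set.seed(21)
  # large-sample approximation close to enumeration at n=8 per group:
  # median deviation below 0.01; the absolute worst case of the
  # continuity-corrected approximation is ~0.011, bounded here at 0.02
  diffs <- replicate(50, {
    x <- rnorm(8); y <- rnorm(8, mean = 0.5)
    p_exact <- wilcoxon_rank_sum(x, y, exact_max_n = 10)
    expect_equal(p_exact, enum_ranksum_p(x, y), tolerance = 1e-12)
    abs(p_exact - wilcoxon_rank_sum(x, y, exact_max_n = 0))
  })
  expect_lt(median(diffs), 0.01)
  expect_lt(max(diffs), 0.02)
})

test_that("shift_per_celltype scores big clusters and reports skips", {
  set.seed(30)
  n <- 300
  coords <- rbind(matrix(rnorm(n * 3), n, 3),            # cluster T, case
                  matrix(rnorm(n * 3), n, 3),            # cluster T, control
                  matrix(rnorm(20 * 3), 20, 3))          # cluster rare
  rownames(coords) <- sprintf("bc%04d", seq_len(nrow(coords)))
  ann <- data.frame(
    barcode = rownames(coords),
    sample_id = "s",
    condition = c(rep("case", n), rep("control", n),
                  rep(c("case", "control"), 10)),
    cluster = c(rep("T", 2 * n), rep("rare", 20)),
    stringsAsFactors = FALSE)
  scheme <- subsample_scheme(n_sub = 100, n_reps = 20, min_cluster_size = 100,
                             seed = 5)
  res <- shift_per_celltype(embedding(coords), ann, scheme)
  expect_named(res$results, "T")
  tab <- res$table
  expect_true(tab$skipped[tab$cell_type == "rare"])
  expect_match(tab$reason[tab$cell_type == "rare"], "min_cluster_size")
  expect_false(tab$skipped[tab$cell_type == "T"])
  # replicate table is long-format with all three kinds
  long <- shift_replicate_table(res$results)
  expect_setequal(unique(long$kind), c("observed", "null", "normalized"))
  expect_equal(nrow(long), 3 * 20)
  # adding another cluster does not perturb the existing stream
  res2 <- shift_per_celltype(embedding(coords), ann, scheme, clusters = "T")
  expect_identical(res2$results$T$observed, res$results$T$observed)
})
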