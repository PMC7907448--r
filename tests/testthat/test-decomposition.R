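test_that("centering removes gene means and keeps them for projection", {
  vals <- matrix(c(1, 5, 3, 5), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ce <- center_expression(toy_log_expr(vals))
  expect_equal(unname(ce$matrix[, "g1"]), c(-1, 1))
  expect_equal(unname(ce$gene_means), c(2, 5))
  expect_equal(unname(ce$matrix[, "g2"]), c(0, 0))

  set.seed(5)
  m <- matrix(rnorm(20), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  ce2 <- center_expression(toy_log_expr(m))
  expect_lt(max(abs(colMeans(ce2$matrix))), 1e-12)

  one <- matrix(1, 1, 1, dimnames = list("g", "s"))
  expect_error(center_expression(toy_log_expr(t(one))), "2 samples")
})

test_that("svd_pca reconstructs its input and normalizes variance", {
  # orthogonal 2x2: singular values both 1
  x <- matrix(c(1, 0, 0, -1), 2,
              dimnames = list(c("ga", "gb"), c("sa", "sb")))
  ce <- structure(list(matrix = t(x), gene_means = c(ga = 0, gb = 0),
                       gene_ids = c("ga", "gb"), sample_ids = c("sa", "sb"),
                       pseudocount = 1, provenance = "test"),
                  class = "centered_expr")
  d <- svd_pca(ce)
  expect_equal(d$singular_values, c(1, 1))
  recon <- d$scores %*% t(d$loadings)
  expect_lt(max(abs(recon - t(x))), 1e-12)

  # rank-1 outer product: second singular value vanishes
  u <- c(1, 2, 3); v <- c(2, -1, 0, 4)
  r1 <- outer(u, v)
  dimnames(r1) <- list(paste0("s", 1:3), paste0("g", 1:4))
  ce1 <- structure(list(matrix = sweep(r1, 2, colMeans(r1)),
                        gene_means = colMeans(r1),
                        gene_ids = colnames(r1), sample_ids = rownames(r1),
                        pseudocount = 1, provenance = "test"),
                   class = "centered_expr")
  d1 <- svd_pca(ce1)
  expect_lt(d1$singular_values[2], 1e-10)

  # random matrix: identity checks
  set.seed(9)
  m <- matrix(rnorm(20 * 60), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:20)))
  d2 <- fit_trajectory_pca(toy_log_expr(m))
  V <- d2$loadings
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  centered <- sweep(t(m), 2, d2$gene_means)
  expect_lt(max(abs(d2$scores %*% t(V) - centered)), 1e-8)
  expect_equal(sum(d2$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(d2$singular_values) <= 1e-12))
})

test_that("component signs are deterministic and permutation-equivariant", {
  set.seed(21)
  m <- matrix(rnorm(15 * 40), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:15)))
  le <- toy_log_expr(m)
  d1 <- fit_trajectory_pca(le)
  d2 <- fit_trajectory_pca(le)
  expect_identical(d1$loadings, d2$loadings)

  perm <- sample(ncol(m))
  le_p <- toy_log_expr(m[, perm])
  d3 <- fit_trajectory_pca(le_p)
  # compare components above numerical rank: with 15 samples the centered
  # matrix has rank 14 and the null-space direction is arbitrary
  r <- sum(d1$singular_values > 1e-8)
  expect_equal(d3$loadings[, 1:r], d1$loadings[, 1:r], tolerance = 1e-9)
  expect_equal(d3$singular_values, d1$singular_values, tolerance = 1e-9)
  expect_equal(d3$scores[rownames(d1$scores), 1:r], d1$scores[, 1:r],
               tolerance = 1e-9)
})

test_that("trajectory curves have one series per condition-replicate", {
  set.seed(2)
  design <- sample_design(expand.grid(
    replicate = c("r1", "r2"), time_h = c(0, 6, 24), condition = c("A", "B"),
    stringsAsFactors = FALSE) |> transform(
      sample_id = paste(condition, time_h, replicate, sep = "_"),
      dataset = "toy"))
  m <- matrix(rnorm(10 * 12), nrow = 10,
              dimnames = list(paste0("g", 1:10), design$sample_id))
  d <- fit_trajectory_pca(toy_log_expr(m))
  tr <- trajectory_curves(d, design, 1)
  series <- split(tr$curves, paste(tr$curves$condition, tr$curves$replicate))
  expect_length(series, 4)
  expect_true(all(vapply(series, nrow, 1L) == 3))
  expect_true(all(vapply(series, function(s) all(diff(s$time_h) > 0), TRUE)))
  expect_setequal(tr$curves$sample_id, design$sample_id)
  expect_equal(nrow(tr$condition_means), 6)

  expect_error(trajectory_curves(d, design[-1, ], 1), "missing from design")
})

test_that("diagnostics capture time correlation, divergence and spikes", {
  # scores proportional to time give Spearman rho = 1 on that component
  design <- sample_design(data.frame(
    sample_id = paste0("s", 1:12),
    condition = rep(c("A", "B"), each = 6),
    time_h = rep(c(0, 4, 8), 4),
    replicate = rep(rep(c("r1", "r2"), each = 3), 2),
    dataset = "toy"))
  scores <- cbind(PC1 = design$time_h,
                  PC2 = rep(c(1, -1), 6))
  rownames(scores) <- design$sample_id
  d <- structure(list(sample_ids = design$sample_id, scores = scores,
                      variance_fraction = c(0.7, 0.3)),
                 class = "pca_decomp")
  diag <- component_diagnostics(d, design, c("A", "B"))
  expect_equal(diag$time_correlation[1], 1)
  expect_equal(diag$variance_fraction, c(0.7, 0.3))

  # exchangeable conditions: divergence stays small on every component
  set.seed(31)
  avg <- replicate(20, {
    sim_scores <- matrix(rnorm(24), nrow = 12,
                         dimnames = list(design$sample_id, c("PC1", "PC2")))
    dd <- structure(list(sample_ids = design$sample_id, scores = sim_scores,
                         variance_fraction = c(0.5, 0.5)),
                    class = "pca_decomp")
    mean(component_diagnostics(dd, design, c("A", "B"))$divergence_score)
  })
  expect_lte(mean(avg), 1.5)

  expect_error(component_diagnostics(d, design, c("A", "B", "C")),
               "two distinct")
})

test_that("divergent component selection is a gated argmax with index ties", {
  diag <- structure(data.frame(component = 1:3,
                               variance_fraction = c(0.5, 0.3, 0.2),
                               time_correlation = c(0.2, 0.1, 0.9),
                               divergence_score = c(0.1, 2.0, 3.0),
                               spike_score = 0),
                    class = c("component_diag", "data.frame"))
  expect_equal(select_divergent_component(diag, max_time_corr = 0.8), 2)
  diag$divergence_score <- c(2.0, 2.0, 3.0)
  expect_equal(select_divergent_component(diag, max_time_corr = 0.8), 1)
  diag$time_correlation <- c(0.9, 0.95, 0.9)
  expect_error(select_divergent_component(diag, max_time_corr = 0.8),
               "max_time_corr")
})

test_that("eigengene ranking orders by |loading| with lexicographic ties", {
  loadings <- cbind(PC1 = c(A = 0.9, B = -0.95, C = 0.1))
  d <- structure(list(loadings = loadings), class = "pca_decomp")
  rk <- rank_eigengenes(d, 1)
  expect_identical(rk$gene_id, c("B", "A", "C"))
  expect_identical(rk$rank, 1:3)
  expect_true(all(diff(rk$abs_loading) <= 0))

  loadings2 <- cbind(PC1 = c(Z = 0.5, A = -0.5, M = 0.2))
  d2 <- structure(list(loadings = loadings2), class = "pca_decomp")
  rk2 <- rank_eigengenes(d2, 1)
  expect_identical(rk2$gene_id, c("A", "Z", "M"))
})

test_that("null flow labels do not produce significant divergence", {
  # both conditions share every program: the selected divergence score should
  # sit inside its label-permutation distribution
  cfg <- small_config(n_divergent = 0)
  set.seed(77)
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_timecourse(cfg, seed = 400 + s)
    d <- fit_sim(sim)
    diag <- component_diagnostics(d, sim$design, c("PS", "OS"))
    sel <- select_divergent_component(diag)
    obs <- diag$divergence_score[sel]
    gate <- abs(diag$time_correlation) <= 0.8
    perm_max <- vapply(1:19, function(b) {
      des <- sim$design
      for (t in unique(des$time_h)) {
        idx <- which(des$time_h == t)
        des$condition[idx] <- sample(des$condition[idx])
      }
      dg <- component_diagnostics(d, des, c("PS", "OS"))
      max(dg$divergence_score[abs(dg$time_correlation) <= 0.8])
    }, numeric(1))
    (1 + sum(perm_max >= obs)) / 20
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.8)
})
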