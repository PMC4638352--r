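test_that("univariate block reduces to the absolute Pearson correlation", {
  set.seed(1)
  x <- matrix(runif(50), ncol = 1, dimnames = list(NULL, "cg1"))
  y <- 3 - 2 * x[, 1] + rnorm(50, sd = 0.3)
  cc <- canonical_correlation(x, y)
  expect_equal(cc$r, abs(cor(x[, 1], y)), tolerance = 1e-12)
  expect_equal(cc$beta_sign, -1L)
})

test_that("an exact linear relationship gives r = 1", {
  set.seed(2)
  X <- matrix(runif(80), ncol = 2, dimnames = list(NULL, c("cg1", "cg2")))
  y <- 2 * X[, 1] - X[, 2]
  cc <- canonical_correlation(X, y)
  expect_equal(cc$r, 1, tolerance = 1e-10)
})

test_that("closed form agrees with the exhaustive grid-search oracle for p <= 3", {
  set.seed(3)
  for (p in 2:3) {
    for (rep in 1:3) {
      X <- matrix(runif(40 * p), ncol = p,
                  dimnames = list(NULL, paste0("cg", 1:p)))
      y <- rnorm(40) + X %*% runif(p, -2, 2)
      cc <- canonical_correlation(X, y)
      expect_equal(cc$r, grid_search_r(X, y), tolerance = 1e-3)
    }
  }
})

test_that("the canonical variate has unit variance and dominates the equal-weight mix", {
  set.seed(4)
  X <- matrix(runif(200), ncol = 4, dimnames = list(NULL, paste0("cg", 1:4)))
  y <- X %*% c(1, -1, 0.5, 0) + rnorm(50, sd = 0.5)
  cc <- canonical_correlation(X, y)
  u <- scale(X, center = cc$means, scale = FALSE) %*% cc$alpha
  expect_equal(var(drop(u)), 1, tolerance = 1e-10)
  expect_gte(cc$r, abs(cor(rowMeans(X), y)) - 1e-10)
})

test_that("r is invariant to positive rescaling of columns or expression", {
  set.seed(5)
  X <- matrix(runif(90), ncol = 3, dimnames = list(NULL, paste0("cg", 1:3)))
  y <- rnorm(30) + X[, 1]
  r0 <- canonical_correlation(X, y)$r
  X2 <- sweep(X, 2, c(3, 0.2, 7), `*`)
  expect_equal(canonical_correlation(X2, y)$r, r0, tolerance = 1e-10)
  expect_equal(canonical_correlation(X, 100 * y)$r, r0, tolerance = 1e-10)
})

test_that("flipping the sign of expression flips beta_sign, not r or the weights", {
  set.seed(6)
  X <- matrix(runif(120), ncol = 3, dimnames = list(NULL, paste0("cg", 1:3)))
  y <- X %*% c(1, 1, -0.5) + rnorm(40, sd = 0.2)
  a <- canonical_correlation(X, y)
  b <- canonical_correlation(X, -y)
  expect_equal(b$r, a$r, tolerance = 1e-12)
  expect_equal(b$alpha, a$alpha, tolerance = 1e-12)
  expect_equal(b$beta_sign, -a$beta_sign)
})

test_that("compute_mps is the stated linear score", {
  # raw projection with centering disabled
  expect_equal(compute_mps(c(1, 0), matrix(c(0.4, 0.9), nrow = 1)), 0.4)

  # elementwise oracle on a 5-CpG block
  set.seed(7)
  alpha <- setNames(rnorm(5), paste0("cg", 1:5))
  X <- matrix(runif(60), ncol = 5, dimnames = list(NULL, paste0("cg", 1:5)))
  ctr <- setNames(runif(5), paste0("cg", 1:5))
  manual <- apply(X, 1, function(row) sum(alpha * (row - ctr)))
  expect_equal(unname(compute_mps(alpha, X, center = ctr)), manual, tolerance = 1e-12)

  # column order in new data must not matter
  expect_equal(compute_mps(alpha, X[, 5:1], center = ctr),
               compute_mps(alpha, X, center = ctr))

  expect_error(compute_mps(alpha, X[, 1:3]), "cg4")
})

test_that("average-methylation correlation matches the direct formula", {
  set.seed(8)
  x <- matrix(runif(30), ncol = 1)
  y <- rnorm(30)
  expect_equal(average_methylation_correlation(x, y), cor(x[, 1], y))

  X <- matrix(runif(90), ncol = 3)
  expect_equal(average_methylation_correlation(X, rowMeans(X)), 1)
  expect_equal(average_methylation_correlation(X, y),
               cor(rowMeans(X), y), tolerance = 1e-14)
})

test_that("per-gene patterns cover eligible genes and reproduce training MPS", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 2, n_planted = 0, seed = 21))
  pats <- per_gene_patterns(co$meth, co$expr, co$pmap)
  expect_length(pats, 2)
  for (p in pats) {
    expect_equal(unname(compute_mps(p$alpha, co$meth, center = p$means)),
                 unname(p$mps))
    expect_gte(p$r, abs(p$pearson_avg) - 1e-8)
    expect_equal(var(p$mps), 1, tolerance = 1e-8)
  }
})

test_that("regulatory direction is recovered when expression noise vanishes", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_genes = 20, n_planted = 10,
                                   noise_sd = 1e-4, seed = 31))
  pats <- per_gene_patterns(co$meth, co$expr, co$pmap)
  est <- vapply(pats, `[[`, integer(1), "beta_sign")
  expect_equal(unname(est[co$truth$gene_id]), co$truth$sign)
})

test_that("weight direction is recovered under high signal-to-noise", {
  co <- simulate_cohort(sim_config(n_samples = 150, n_genes = 100, n_planted = 0,
                                   noise_sd = 0.05, seed = 41))
  pats <- per_gene_patterns(co$meth, co$expr, co$pmap)
  cosims <- vapply(co$truth$gene_id, function(g) {
    w_true <- as.numeric(strsplit(co$truth$weights[co$truth$gene_id == g], ",")[[1]])
    a <- pats[[g]]$alpha
    abs(sum(a * w_true)) / sqrt(sum(a^2) * sum(w_true^2))
  }, numeric(1))
  expect_gte(median(cosims), 0.9)
})

test_that("canonical r dominates the average-methylation correlation gene-wide", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_genes = 200, n_planted = 0,
                                   seed = 51))
  pats <- per_gene_patterns(co$meth, co$expr, co$pmap)
  expect_length(pats, 200)
  r <- vapply(pats, `[[`, numeric(1), "r")
  pa <- vapply(pats, `[[`, numeric(1), "pearson_avg")
  expect_true(all(r >= abs(pa) - 1e-8))
})

test_that("degenerate inputs are rejected or skipped as specified", {
  X <- matrix(0.5, nrow = 10, ncol = 2, dimnames = list(NULL, c("cg1", "cg2")))
  expect_error(canonical_correlation(X, rnorm(10)), "constant")
  Xv <- matrix(runif(20), ncol = 2, dimnames = list(NULL, c("cg1", "cg2")))
  expect_error(canonical_correlation(Xv, rep(1, 10)), "constant")
})
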