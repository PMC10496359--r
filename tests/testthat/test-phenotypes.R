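test_that("standardization is the log-ratio to the reference and inverts", {
  raw <- matrix(c(1, 2, 1 / exp(1), 4, 0.5, 8), 3, 2,
                dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  ref <- c(t1 = 1, t2 = 4)
  out <- standardize_traits(raw, ref)
  expect_equal(out["a", "t1"], 0)                 # raw == reference
  expect_equal(out["b", "t1"], log(2), tolerance = 1e-12)
  expect_equal(out["c", "t1"], -1)                # reference / e
  # invertibility: exp(out) * ref reproduces raw
  back <- sweep(exp(unclass(out)), 2L, ref, "*")
  expect_equal(back, raw, tolerance = 1e-12)
})

test_that("standardization validates inputs and supports a reference row", {
  raw <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("wt", "mut"), c("t1", "t2")))
  expect_error(standardize_traits(raw, c(t1 = 1)), "lacks traits")
  raw_bad <- raw; raw_bad["mut", "t2"] <- -1
  expect_error(standardize_traits(raw_bad, c(t1 = 1, t2 = 1)),
               "unit 'mut', trait 't2'")
  expect_error(standardize_traits(raw, c(t1 = 0, t2 = 1)),
               "non-positive reference")
  # reference named by row ID: row consumed as the reference and dropped
  raw3 <- rbind(raw, ctrl = c(1, 2))
  out <- standardize_traits(raw3, "ctrl")
  expect_equal(rownames(out), c("wt", "mut"))
  expect_equal(out["wt", "t2"], log(3 / 2), tolerance = 1e-12)
})

test_that("mutational correlation recovers exact and sampled dependence", {
  x <- cbind(1:6, 3 * (1:6) + 2, -(1:6))
  res <- mutational_correlation(toy_table(x))
  expect_equal(res$correlation[1, 2], 1)
  expect_equal(res$correlation[1, 3], -1)
  expect_equal(res$n, 6)
  # sampled bivariate normal, rho = 0.5: estimate within sampling error
  panel <- gen_mutant_panel(5000, equicorr(2, 0.5), seed = 101)
  est <- mutational_correlation(panel)$correlation[1, 2]
  expect_lt(abs(est - 0.5), 0.03)
})

test_that("mutational correlation is affine- and row-order-invariant and
           its covariance matches a two-pass computation", {
  set.seed(7)
  x <- matrix(rnorm(40), 8, 5)
  tt <- toy_table(x)
  base <- mutational_correlation(tt)
  # per-trait affine rescaling (positive scale) leaves correlations unchanged
  y <- sweep(sweep(x, 2L, c(2, 0.5, 3, 10, 0.1), "*"), 2L, rnorm(5), "+")
  expect_equal(mutational_correlation(toy_table(y))$correlation,
               base$correlation, tolerance = 1e-12)
  # row order
  perm <- sample(8)
  expect_equal(
    mutational_correlation(trait_table(unclass(tt)[perm, ]))$correlation,
    base$correlation, tolerance = 1e-12)
  # brute-force two-pass covariance
  mu <- colMeans(x)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    brute[i, j] <- sum((x[, i] - mu[i]) * (x[, j] - mu[j])) / (8 - 1)
  dimnames(brute) <- dimnames(base$covariance)
  expect_equal(base$covariance, brute, tolerance = 1e-12)
})

test_that("mutational correlation rejects degenerate input and drops
           incomplete lines", {
  x <- cbind(rep(1, 5), rnorm(5))
  expect_error(mutational_correlation(toy_table(x)), "zero-variance.*t1")
  x2 <- matrix(rnorm(12), 6, 2)
  x2[2, 1] <- NA
  tt <- trait_table(matrix(x2, 6, 2,
                           dimnames = list(paste0("u", 1:6), c("a", "b"))),
                    allow_missing = TRUE)
  expect_message(res <- mutational_correlation(tt), "1 line")
  expect_equal(res$n, 5)
  expect_error(mutational_correlation(toy_table(matrix(rnorm(6), 3, 2))),
               "at least 4")
})

test_that("bias coefficient follows the max/min square-root convention", {
  expect_equal(estimate_bias_coefficient(c(1, 3, -1, -1)), sqrt(2),
               tolerance = 1e-12)
  expect_equal(estimate_bias_coefficient(c(1, -1, 2, -2)), 1)
  expect_equal(estimate_bias_coefficient(c(4, -1)), 2)
  expect_error(estimate_bias_coefficient(c(1, 2, 3)), "both signs")
  # sign symmetry: flipping all values leaves B unchanged
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(30, mean = runif(1, -0.5, 0.5))
    if (all(v > 0) || all(v < 0)) next
    expect_equal(estimate_bias_coefficient(v), estimate_bias_coefficient(-v),
                 tolerance = 1e-12)
  }
})

test_that("sampling-error check shows stable eigenstructure at large n", {
  M <- diag(c(4, 1, 0.25))
  dimnames(M) <- list(paste0("t", 1:3), paste0("t", 1:3))
  r <- matrix_sampling_error_check(M, n_samples = 10000, n_reps = 40,
                                   seed = 5)
  expect_length(r, 40)
  expect_true(all(r > 0.99))
  # determinism under a fixed seed
  expect_identical(r, matrix_sampling_error_check(M, 10000, 40, seed = 5))
  # 2 traits: only two eigenvalues, so each correlation is +1 or -1, and at
  # n = 5000 the eigenvalue order is almost always preserved
  M2 <- diag(c(2, 0.5))
  dimnames(M2) <- list(c("a", "b"), c("a", "b"))
  r2 <- matrix_sampling_error_check(M2, n_samples = 5000, n_reps = 200,
                                    seed = 6)
  expect_true(all(r2 %in% c(-1, 1)))
  expect_gt(mean(r2 == 1), 0.95)
  # degenerate M: all eigenvalues equal
  expect_warning(r3 <- matrix_sampling_error_check(diag(2), 100, 3, seed = 1),
                 "undefined")
  expect_true(all(is.nan(r3)))
})

test_that("PC envelope check localizes a query against replicate clouds", {
  set.seed(21)
  # 3-factor model: loadings on 8 traits, small residual noise
  load <- matrix(rnorm(24, sd = 2), 8, 3)
  scores <- matrix(rnorm(300), 100, 3)
  reps <- scores %*% t(load) + matrix(rnorm(800, sd = 0.1), 100, 8)
  tt <- toy_table(reps)
  ctr <- colMeans(reps)
  ok <- pc_envelope_check(tt, ctr, n_pcs = 3)
  expect_true(all(ok$per_pc$inside))
  expect_equal(ok$per_pc$projection, rep(0, 3), tolerance = 1e-10)
  expect_gt(ok$variance_explained, 0.9)
  # query shifted 10 sample-sd along PC1 -> outside on PC1
  pca <- prcomp(reps, center = TRUE)
  far <- ctr + 10 * sd(pca$x[, 1]) * pca$rotation[, 1]
  shifted <- pc_envelope_check(tt, far, n_pcs = 3)
  expect_false(shifted$per_pc$inside[1])
  expect_error(pc_envelope_check(tt, ctr, n_pcs = 9), "rank|replicate rows")
})
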