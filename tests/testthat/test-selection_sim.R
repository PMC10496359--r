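test_that("mutational covariance matrix construction", {
  expect_equal(build_m_matrix(0.01, 0), diag(c(0.01, 0.01)),
               ignore_attr = TRUE)
  m <- build_m_matrix(0.01, 0.5)
  expect_equal(m[1, 2], 0.005)
  expect_equal(det(build_m_matrix(0.01, 1)), 0, tolerance = 1e-12)
  expect_error(build_m_matrix(0.01, 1.2), "cor_m")
})

test_that("Gaussian fitness on points and ridges", {
  ridge <- selection_regime("ridge", slope = 1)
  point <- selection_regime("point", optimum = c(0, 0))
  expect_equal(fitness(c(2, 2), ridge), 1)        # on the ridge
  expect_equal(fitness(c(0, 0), point), 1)        # at the optimum
  expect_equal(fitness(c(1, 0), point), exp(-0.5), tolerance = 1e-12)
  expect_equal(fitness(c(1, 0), ridge), exp(-0.25), tolerance = 1e-12)
  ridge_half <- selection_regime("ridge", slope = 0.5)
  d <- abs(3 - 0.5 * 2) / sqrt(1.25)
  expect_equal(fitness(c(2, 3), ridge_half), exp(-d^2 / 2), tolerance = 1e-12)
  expect_error(fitness(c(0, 0), selection_regime("none")), "no fitness")
})

test_that("fixation probability is stable, monotone, and matches worked
           values", {
  expect_equal(fixation_probability(0, 1e4), 1e-4)
  expect_equal(fixation_probability(1e-15, 1e4), 1e-4)  # s -> 0 limit
  expect_equal(fixation_probability(0.01, 1e4), 0.0198013,
               tolerance = 1e-5)
  expect_equal(fixation_probability(-0.01, 1e4), 2.795656e-89,
               tolerance = 1e-5)
  expect_equal(fixation_probability(-10, 1e4), 0)     # underflow-safe
  expect_equal(fixation_probability(50, 1e4), 1, tolerance = 1e-12)
  s_grid <- c(-0.5, -0.1, -0.01, -1e-4, -1e-8, 0, 1e-8, 1e-4, 0.01, 0.1, 0.5)
  pf <- fixation_probability(s_grid, 1e4)
  expect_true(all(diff(pf) >= 0))
  expect_true(all(pf >= 0 & pf <= 1))
  # agrees with the naive formula where it is numerically safe
  safe <- c(-1e-3, 1e-4, 5e-4, 1e-3, 5e-3)
  naive <- (1 - exp(-2 * safe)) / (1 - exp(-2 * 1e4 * safe))
  expect_equal(fixation_probability(safe, 1e4), naive, tolerance = 1e-9)
})

test_that("bias rescaling multiplies or divides both components by B", {
  expect_equal(rescale_mutation(c(0.3, -0.2), 1), c(0.3, -0.2))
  expect_equal(rescale_mutation(c(0.3, -0.2), 1.5), c(0.45, -0.3))
  expect_equal(rescale_mutation(c(-0.3, 0.2), 1.5), c(-0.2, 0.2 / 1.5),
               tolerance = 1e-12)
  expect_equal(rescale_mutation(c(0, 5), 2), c(0, 5))   # m1 = 0 untouched
  # sign pattern and component ratio preserved exactly (matrix form)
  set.seed(13)
  m <- matrix(rnorm(40), 20, 2)
  r <- rescale_mutation(m, 1.7)
  expect_equal(sign(r), sign(m))
  expect_equal(r[, 2] / r[, 1], m[, 2] / m[, 1], tolerance = 1e-12)
})

test_that("one neutral time step adds Poisson-compounded mutational
           variance", {
  cfg <- sim_config(cor_m = 0, v_m = 0.01)
  none <- selection_regime("none")
  set.seed(17)
  x <- replicate(4000, {
    st <- step_lineage(list(mean = c(0, 0), n_fixed = 0L), cfg, none)
    st$mean[1]
  })
  expect_equal(var(x), 0.01, tolerance = 0.15)  # E[N] * V_M with N ~ Pois(1)
})

test_that("regime simulation is seed-reproducible and recovers the neutral
           and ridge regimes", {
  cfg <- function(cm, reps = 40, time = 300, seed = 23)
    sim_config(cor_m = cm, n_reps = reps, time_units = time, seed = seed)
  r1 <- simulate_regime(cfg(0.5), selection_regime("none"))
  r2 <- simulate_regime(cfg(0.5), selection_regime("none"))
  expect_identical(r1$cor_e, r2$cor_e)
  # neutral: mean COR_E within 2.5 s.e. of COR_M for each COR_M
  for (cm in c(0.1, 0.5, 0.9)) {
    r <- simulate_regime(cfg(cm, seed = 23 + round(10 * cm)),
                         selection_regime("none"))
    se <- sd(r$cor_e) / sqrt(length(r$cor_e))
    expect_lt(abs(mean(r$cor_e) - cm), 2.5 * se)
    expect_equal(r$verdict, "no_difference")
  }
  # ridge: correlation driven to |1| once lineages spread along the line
  up <- simulate_regime(cfg(0.1, reps = 25, time = 400),
                        selection_regime("ridge", slope = 1))
  expect_gt(up$median, 0.99)
  expect_equal(up$verdict, "strengthened")
  dn <- simulate_regime(cfg(0.5, reps = 25, time = 400),
                        selection_regime("ridge", slope = -0.5))
  expect_lt(dn$median, -0.99)
  expect_equal(dn$verdict, "reversed")
  # point optimum: strong stabilizing selection pins the means, weakening
  # the across-lineage correlation
  pt <- simulate_regime(cfg(0.9, reps = 40, time = 400),
                        selection_regime("point", optimum = c(0, 0)))
  expect_lt(abs(pt$median), 0.2)
  expect_equal(pt$verdict, "weakened")
})

test_that("bias rescaling leaves the estimated mutational correlation near
           its pre-set value", {
  b1 <- bias_cor_check(0.5, bias = 1, n_reps = 60, seed = 3)
  expect_lt(abs(b1$median - 0.5), 0.02)
  b0 <- bias_cor_check(0, bias = 1.7, n_reps = 60, seed = 4)
  expect_lt(abs(b0$median), 0.02)
  bb <- bias_cor_check(0.5, bias = 1.5, n_reps = 200, seed = 5)
  expect_gt(bb$quantile_of_cor_m, 0.05)
  expect_lt(bb$quantile_of_cor_m, 0.95)
  expect_error(bias_cor_check(0.5, 1.5, n_mutations = 3), "at least 4")
})
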