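test_that("dominance-decay constant k matches a Monte-Carlo oracle", {
  expect_equal(solve_k(0.3, 0.2, 0.5), 0)
  k <- solve_k(0.3, 0.2, 0.25)
  expect_gt(k, 0)
  # larger k must mean smaller mean dominance
  k_low <- solve_k(0.3, 0.2, 0.1)
  expect_gt(k_low, k)
  # sampling oracle: mean of exp(-k s) over truncated gamma draws is 2 h_mean
  set.seed(1)
  s <- pmin(rgamma(1e6, shape = 0.2, scale = 0.3 / 0.2), 1)
  m <- mean(exp(-k * s))
  se <- sd(exp(-k * s)) / sqrt(1e6)
  expect_lt(abs(m - 0.5), max(1e-3, 3 * se))
  expect_error(solve_k(0.3, 0.2, 0.6), "infeasible")
})

test_that("equilibrium frequencies satisfy the recurrence and classical limits", {
  # recessive limit q ~ sqrt(u/s)
  expect_equal(equilibrium_frequency(1, 0, 1e-5), sqrt(1e-5),
               tolerance = 0.05)
  # partially dominant limit q ~ u/(sh)
  expect_equal(equilibrium_frequency(0.1, 0.25, 1e-5), 1e-5 / 0.025,
               tolerance = 0.05)
  # vanishing mutation pressure
  expect_lt(equilibrium_frequency(0.5, 0.2, 1e-30), 1e-25)
  # the returned frequency is a fixed point of the recurrence
  grid <- expand.grid(s = c(0.001, 0.01, 0.1, 0.5, 1),
                      h = c(0, 0.05, 0.25, 0.5, 0.8),
                      u = c(1e-6, 1e-5, 1e-3))
  q <- equilibrium_frequency(grid$s, grid$h, grid$u)
  expect_true(all(abs(msb_residual(q, grid$s, grid$h, grid$u)) <= 1e-10))
  # monotone: increasing in u, decreasing in h at fixed s
  qs_u <- equilibrium_frequency(0.2, 0.25, c(1e-7, 1e-6, 1e-5, 1e-4))
  expect_true(all(diff(qs_u) > 0))
  qs_h <- equilibrium_frequency(0.2, c(0.01, 0.1, 0.3, 0.5), 1e-5)
  expect_true(all(diff(qs_h) < 0))
  expect_error(equilibrium_frequency(0, 0.2, 1e-5), "neutral")
})

test_that("selection weaker than mutation pressure drives fixation", {
  q <- equilibrium_frequency(1e-9, 0.3, 1e-5)
  expect_equal(q, 1)
  expect_equal(locus_load(1e-9, 0.3, q), 0)
})

test_that("locus load follows the Morton decomposition", {
  expect_equal(locus_load(1, 0, 0.5), 0.25)
  expect_equal(locus_load(0.7, 0.5, 0.3), 0)   # additive: nothing concealed
  expect_equal(locus_load(0.7, 0.1, 0), 0)
  expect_equal(locus_load(0.7, 0.1, 1), 0)
  g <- genome_manual(s = c(0.5, 0.5), h = c(0.1, 0.1), q_hat = c(0.02, 0.02))
  expect_equal(genome_load(g), 2 * locus_load(0.5, 0.1, 0.02))
  g0 <- genome_manual(s = numeric(0), h = numeric(0))
  expect_equal(genome_load(g0), 0)
})

test_that("sampled genomes respect their family rules", {
  neutral <- sample_dfe(dfe_model("neutral", L = 100), seed = 1)
  expect_true(all(neutral$s == 0))
  expect_true(all(neutral$load == 0))
  kim <- sample_dfe(dfe_model("kim_piecewise_h", L = 3000), seed = 2)
  expect_true(all(kim$h %in% c(0, 0.25)))
  expect_true(all((kim$h == 0.25) == (kim$s < 0.02)))
  # lethal-class mass matches the gamma tail
  m <- dfe_model("gamma_uniform_h", s_mean = 0.3, h_mean = 0.25, L = 2e5)
  g <- sample_dfe(m, seed = 3)
  p_tail <- pgamma(1, shape = 0.2, scale = 0.3 / 0.2, lower.tail = FALSE)
  se <- sqrt(p_tail * (1 - p_tail) / 2e5)
  expect_lt(abs(mean(g$s == 1) - p_tail), 3 * se)
  # mean s converges to the truncated-gamma mean
  sc <- 0.3 / 0.2
  m_trunc <- integrate(function(s) s * dgamma(s, 0.2, scale = sc), 0, 1,
                       rel.tol = 1e-10)$value + p_tail
  expect_lt(abs(mean(g$s) - m_trunc), 3 * sd(g$s) / sqrt(2e5))
  # mean h converges to the target after k-solving
  expect_lt(abs(mean(g$h) - 0.25), 3 * sd(g$h) / sqrt(2e5))
  # determinism
  expect_identical(sample_dfe(m, seed = 3)$s, g$s)
})

test_that("the load share below a cutoff is a monotone fraction", {
  m <- dfe_model("gamma_uniform_h", s_mean = 0.2, h_mean = 0.25, L = 5000)
  g <- sample_dfe(m, seed = 5)
  expect_equal(load_fraction_below(g, 2), 1)
  expect_equal(load_fraction_below(g, 0), 0)
  cuts <- c(0.01, 0.05, 0.2, 0.5, 1.001)
  fr <- vapply(cuts, function(ct) load_fraction_below(g, ct), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  g0 <- genome_manual(s = 0.5, h = 0.5, q_hat = 0.1)  # zero total load
  expect_error(load_fraction_below(g0, 0.2), "undefined")
})

test_that("mutation-rate calibration hits its target and scales sensibly", {
  m <- dfe_model("gamma_uniform_h", s_mean = 0.2, h_mean = 0.4, L = 2000)
  cal1 <- calibrate_mutation_rate(m, target_load = 0.5, seed = 7)
  expect_lt(abs(cal1$load - 0.5), 1e-3)
  expect_equal(genome_load(cal1$genome), cal1$load, tolerance = 1e-9)
  cal2 <- calibrate_mutation_rate(m, target_load = 1.0, seed = 7)
  expect_gt(cal2$U, cal1$U)
  # near-linear load in U in the mostly-dominant regime
  expect_lt(abs(cal2$U / cal1$U - 2), 0.6)
  expect_error(calibrate_mutation_rate(m, target_load = 1.0, seed = 7,
                                       bounds = c(1e-4, 2e-4)),
               "unreachable")
})
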