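test_that("Wright's inbreeding coefficient matches its closed form and oracle", {
  expect_identical(wright_inbreeding(1376, 0), 0)
  expect_equal(wright_inbreeding(43, 1), 1 / 86)
  # closed form cross-checked against one-generation iterative accumulation
  expect_equal(wright_inbreeding(43, 153), iter_wright(43, 153)[154],
               tolerance = 1e-12)
  expect_equal(wright_inbreeding(43, 153), 0.832955, tolerance = 1e-5)
  f <- wright_inbreeding(200, 0:50)
  expect_true(all(diff(f) > 0))
  expect_error(wright_inbreeding(-5, 3))
  expect_error(wright_inbreeding(43, -1))
})

test_that("purged inbreeding collapses to F for d = 0 and starts at 1/(2Ne)", {
  for (ne in c(20, 43, 1376)) {
    tr <- ip_trajectory(ip_params(ne, d = 0), 100)
    expect_equal(tr$g, tr$F, tolerance = 1e-10)
  }
  for (d in c(0, 0.1, 0.3, 0.5)) {
    tr <- ip_trajectory(ip_params(43, d = d), 2)
    expect_equal(tr$g[2], 1 / 86, tolerance = 1e-12)
    expect_identical(tr$g[1], 0)
  }
})

test_that("purged inbreeding stays within [0, F] and reaches its asymptote", {
  p <- ip_params(43, d = 0.3)
  tr <- ip_trajectory(p, 5000)
  expect_true(all(tr$g >= 0))
  expect_true(all(tr$g <= tr$F + 1e-14))
  a <- 1 / 86
  fixed_point <- a * (1 - 0.6) / (1 - (1 - a) * (1 - 0.6))
  expect_equal(purged_inbreeding_asymptote(p), fixed_point, tolerance = 1e-12)
  expect_equal(fixed_point, 0.00769, tolerance = 1e-3)
  expect_equal(tr$g[5001], fixed_point, tolerance = 1e-10)
})

test_that("fitness predictions obey their closed forms and orderings", {
  p <- ip_params(43, d = 0.3, delta0 = 1.402, p0 = 1)
  tr <- ip_trajectory(p, 153)
  purg <- predict_mean_fitness(p, tr, "purging")
  neut <- predict_mean_fitness(p, tr, "neutral")
  expect_equal(purg[1], 1)
  expect_equal(neut[1], 1)
  expect_true(all(purg >= neut))
  expect_equal(neut[154], exp(-1.402 * wright_inbreeding(43, 153)),
               tolerance = 1e-12)
  expect_equal(neut[154], 0.3110, tolerance = 5e-4)
  # d = 0: both models identical
  p0 <- ip_params(43, d = 0, delta0 = 1.402, p0 = 1)
  tr0 <- ip_trajectory(p0, 50)
  expect_equal(predict_mean_fitness(p0, tr0, "purging"),
               predict_mean_fitness(p0, tr0, "neutral"))
  # log-linearity in delta0
  p2 <- ip_params(43, d = 0.3, delta0 = 2 * 1.402, p0 = 1)
  tr2 <- ip_trajectory(p2, 153)
  expect_equal(predict_mean_fitness(p2, tr2, "purging"), purg^2,
               tolerance = 1e-12)
  # mismatched trajectory is refused
  expect_error(predict_mean_fitness(p, ip_trajectory(ip_params(50, 0.3), 10)),
               "same Ne")
})

test_that("load predictions: neutral closed form, purging limit and ordering", {
  p <- ip_params(1000, d = 0, delta0 = 1.85)
  neut <- predict_inbreeding_load(p, model = "neutral", t_max = 125)
  expect_equal(neut[126], 1.85 * (1 - wright_inbreeding(1000, 125)),
               tolerance = 1e-12)
  expect_equal(neut[126], 1.738, tolerance = 5e-4)
  expect_equal(neut[1], 1.85)

  pd <- ip_params(43, d = 0.25, delta0 = 1.5)
  tr <- ip_trajectory(pd, 200)
  purg <- predict_inbreeding_load(pd, tr, "purging")
  neu2 <- predict_inbreeding_load(pd, tr, "neutral")
  expect_equal(purg[1], 1.5)                 # t = 0 limit g/F -> 1
  expect_equal(purg[2], neu2[2], tolerance = 1e-12)  # g_1 = F_1
  expect_true(all(purg[-(1:2)] < neu2[-(1:2)]))
  expect_true(all(purg >= 0))
  # affine in delta0 (neutral)
  p3 <- ip_params(1000, d = 0, delta0 = 3.7)
  expect_equal(predict_inbreeding_load(p3, model = "neutral", t_max = 50),
               2 * predict_inbreeding_load(ip_params(1000, 0, 1.85),
                                           model = "neutral", t_max = 50),
               tolerance = 1e-12)
})

test_that("relative line fitness reduces correctly in degenerate cases", {
  b <- ip_params(1376, 0.3, 2.0)
  expect_equal(predict_relative_fitness(b, b, 100, 100, "purging"), 1)
  # a load-free line only gains relative to a declining base
  l0 <- ip_params(43, 0, 0)
  r <- predict_relative_fitness(ip_params(1376, 0, 2.0), l0, 153, 234,
                                "neutral")
  expect_equal(r, exp(2.0 * wright_inbreeding(1376, 234)), tolerance = 1e-12)
  expect_gt(r, 1)
})

test_that("purging coefficient is recovered from noiseless load trajectories", {
  gens <- c(0, 30, 60, 90, 120)
  truth <- ip_params(1376, d = 0.3, delta0 = 2.0)
  dl <- predict_inbreeding_load(truth, model = "purging", t_max = 120)[gens + 1]
  fit <- fit_purging_coefficient(gens, dl, ne = 1376, delta0 = 2.0)
  expect_equal(fit$d, 0.3, tolerance = 2e-3)
  expect_lt(fit$sse, 1e-10)
  # a neutral series maps to d = 0
  dn <- predict_inbreeding_load(ip_params(1376, 0, 2.0),
                                model = "neutral", t_max = 120)[gens + 1]
  expect_equal(fit_purging_coefficient(gens, dn, 1376, 2.0)$d, 0,
               tolerance = 2e-3)
  expect_error(fit_purging_coefficient(numeric(0), numeric(0), 1376, 2.0))
})

test_that("purging coefficient recovery is unbiased under small noise", {
  set.seed(42)
  gens <- c(0, 30, 60, 90, 120)
  truth <- ip_params(1376, d = 0.15, delta0 = 2.0)
  mu <- predict_inbreeding_load(truth, model = "purging",
                                t_max = 120)[gens + 1]
  d_hat <- replicate(60, {
    obs <- mu + rnorm(length(mu), sd = 0.03)
    fit_purging_coefficient(gens, obs, 1376, 2.0, grid_step = 0.005)$d
  })
  expect_lt(abs(mean(d_hat) - 0.15), 0.02)
})
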