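test_that("multiplicative genotype fitness handles the lethal class", {
  g <- genome_manual(s = c(1, 0.5, 0.2), h = c(0.25, 0.1, 0))
  expect_equal(genotype_fitness(c(0L, 0L, 0L), g), 1)
  expect_equal(genotype_fitness(c(1L, 0L, 0L), g), 0.75)
  expect_equal(genotype_fitness(c(2L, 0L, 0L), g), 0)
  expect_equal(genotype_fitness(c(0L, 1L, 2L), g), 0.95 * 0.8)
  # adding a mutant allele can never raise fitness
  pop <- population(rbind(c(0L, 1L, 0L), c(0L, 2L, 0L),
                          c(0L, 1L, 1L), c(0L, 1L, 2L)))
  w <- genotype_fitness(pop, g)
  expect_lt(w[2], w[1])
  expect_lte(w[3], w[1])  # het at a fully recessive locus costs nothing
  expect_lt(w[4], w[3])
})

test_that("Hardy-Weinberg founding reproduces frequencies and load", {
  empty <- genome_manual(s = rep(0.1, 20), h = 0, q_hat = 0)
  p0 <- found_natural_population(empty, 50, seed = 1)
  expect_true(all(p0$geno == 0))

  one <- genome_manual(s = 0.1, h = 0.25, q_hat = 0.5)
  p1 <- found_natural_population(one, 4000, seed = 2)
  freq <- tabulate(p1$geno[, 1] + 1L, 3) / 4000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 4000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  g <- flat_genome(L = 400, q = 0.05)
  nat <- found_natural_population(g, 2000, seed = 3)
  expect_equal(population_load(nat, g), genome_load(g), tolerance = 0.05)
})

test_that("one generation of reproduction respects its contracts", {
  # a fixed mutant locus stays fixed without back mutation
  g <- genome_manual(s = c(0.1, 0.1), h = 0.4, u = 0, q_hat = 0)
  pop <- population(matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 2))
  set.seed(4)
  nxt <- next_generation(pop, g)
  expect_true(all(nxt$geno[, 1] == 2L))
  expect_true(all(nxt$geno[, 2] == 0L))

  # a single fit parent within a sex is every offspring's parent of that sex
  glet <- genome_manual(s = c(1, 0), h = c(0, 0), u = 0, q_hat = 0)
  geno <- matrix(0L, 6, 2)
  geno[2:3, 1] <- 2L               # females 2-3 lethal homozygotes
  geno[1, 2] <- 2L                 # the only fit female carries a marker
  pop <- population(geno)
  set.seed(5)
  nxt <- next_generation(pop, glet)
  expect_true(all(nxt$geno[, 2] >= 1L))  # all offspring inherit the marker

  # extinction when every individual of one sex has zero fitness
  geno2 <- matrix(0L, 6, 2)
  geno2[1:3, 1] <- 2L
  expect_error(next_generation(population(geno2), glet), "extinction")
})

test_that("neutral drift erodes heterozygosity at rate 1/(2N)", {
  n <- 20
  g <- genome_manual(s = rep(0, 60), h = 0, u = 0, q_hat = 0.5)
  set.seed(6)
  n_gen <- 30
  het <- replicate(200, {
    pop <- found_natural_population(g, n)
    for (i in seq_len(n_gen)) pop <- next_generation(pop, g)
    population_heterozygosity(pop)
  })
  expected <- 0.5 * (1 - 1 / (2 * n))^n_gen
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - expected), 3 * se + 0.002)
})

test_that("the full experiment is reproducible and tracks both cohorts", {
  g <- flat_genome(L = 100, q = 0.03, u = 1e-5)
  r1 <- run_experiment(g, n_base = 60, n_line = 20, t_split = 10,
                       t_total = 20, replicates = 5, seed = 12,
                       n_natural = 500)
  r2 <- run_experiment(g, n_base = 60, n_line = 20, t_split = 10,
                       t_total = 20, replicates = 5, seed = 12,
                       n_natural = 500)
  expect_identical(r1, r2)
  base <- r1[r1$pop == "base", ]
  line <- r1[r1$pop == "line", ]
  expect_equal(base$generation, 0:30)
  expect_equal(line$generation, 10:30)
  expect_true(all(r1$delta_mean >= 0))
  expect_true(all(r1$w_mean > 0 & r1$w_mean <= 1))
})

test_that("purging depresses the line load below the drift-only control", {
  m <- dfe_model("gamma_uniform_h", s_mean = 0.3, h_mean = 0.25,
                 U = 0.02, L = 300)
  cal <- calibrate_mutation_rate(m, target_load = 1.5, seed = 21)
  sel <- run_experiment(cal$genome, n_base = 100, n_line = 20, t_split = 0,
                        t_total = 60, replicates = 15, seed = 22,
                        selection = TRUE, n_natural = 1000)
  drift <- run_experiment(cal$genome, n_base = 100, n_line = 20, t_split = 0,
                          t_total = 60, replicates = 15, seed = 22,
                          selection = FALSE, n_natural = 1000)
  at <- function(r, gen) r$delta_mean[r$pop == "line" & r$generation == gen]
  expect_lt(at(sel, 50), at(drift, 50))
  expect_lt(at(sel, 60), at(drift, 60))
})

test_that("fit quality is a mean squared difference over pooled observations", {
  g <- flat_genome(L = 50, q = 0.02)
  sim <- run_experiment(g, n_base = 20, n_line = 10, t_split = 5,
                        t_total = 10, replicates = 3, seed = 30,
                        selection = FALSE, n_natural = 200)
  obs <- data.frame(generation = c(0, 10, 8),
                    pop = c("base", "base", "line"),
                    delta = NA_real_)
  obs$delta <- vapply(seq_len(nrow(obs)), function(i) {
    sim$delta_mean[sim$pop == obs$pop[i] &
                     sim$generation == obs$generation[i]]
  }, numeric(1))
  expect_equal(fit_quality(sim, obs), 0)
  obs2 <- obs
  obs2$delta <- obs$delta + 0.3
  expect_equal(fit_quality(sim, obs2), 0.09, tolerance = 1e-12)
  obs3 <- obs
  obs3$generation[1] <- 99
  expect_error(fit_quality(sim, obs3), "outside")
})
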