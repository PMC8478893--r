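#' Diploid population state
#'
#' A population is an integer dosage matrix (individuals x loci, values
#' 0/1/2 mutant-allele copies) plus a sex label per individual. The two
#' sexes are kept at exactly equal counts ("sex ratio of one"): females
#' occupy the first `N/2` rows by convention.
#'
#' @param geno Integer matrix of dosages, one row per individual.
#' @param female Logical vector flagging females; defaults to the first
#'   half of the rows.
#' @return An object of class `population`.
#' @export
population <- function(geno, female = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  if (n %% 2 != 0) stop("population size must be even (sex ratio of one)")
  if (is.null(female)) female <- seq_len(n) <= n / 2
  stopifnot(length(female) == n, sum(female) == n / 2)
  stopifnot(all(geno >= 0), all(geno <= 2))
  structure(list(geno = geno, female = female, n = n),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals (%d/%d F/M), %d loci\n",
              x$n, sum(x$female), x$n - sum(x$female), ncol(x$geno)))
  invisible(x)
}

.genome_vecs <- function(genome) {
  stopifnot(inherits(genome, "genome_dfe"))
  list(s = as.numeric(genome$s), h = as.numeric(genome$h),
       u = as.numeric(genome$u))
}

#' Multiplicative genotype fitness
#'
#' Fitness of each individual under the multiplicative model: genotype
#' values 1, `1 - s h`, `1 - s` per locus for dosages 0, 1, 2, multiplied
#' across loci. A homozygote at a lethal locus (`s = 1`) has fitness 0.
#'
#' @param pop A [population()] (or a bare dosage matrix / vector).
#' @param genome A `genome_dfe` giving per-locus `s` and `h`.
#' @return Numeric vector of fitness values in `[0, 1]`.
#' @export
genotype_fitness <- function(pop, genome) {
  g <- .genome_vecs(genome)
  geno <- if (inherits(pop, "population")) pop$geno else {
    m <- if (is.matrix(pop)) pop else matrix(pop, nrow = 1)
    storage.mode(m) <- "integer"
    m
  }
  stopifnot(ncol(geno) == length(g$s))
  .genotype_fitness_cpp(geno, g$s, g$h)
}

#' Standing inbreeding load of a population
#'
#' Computes current allele frequencies from the dosages and returns the
#' Morton-style load `sum_l s_l (1 - 2 h_l) p_l q_l`.
#'
#' @inheritParams genotype_fitness
#' @return Inbreeding load in lethal equivalents.
#' @export
population_load <- function(pop, genome) {
  stopifnot(inherits(pop, "population"))
  g <- .genome_vecs(genome)
  .population_load_cpp(pop$geno, g$s, g$h)
}

#' Mean expected heterozygosity of a population
#'
#' Average over loci of `2 p q` from the current allele frequencies; the
#' neutral-drift diagnostic (declines by a factor `1 - 1/(2N)` per
#' generation in expectation).
#'
#' @param pop A [population()].
#' @return Mean expected heterozygosity.
#' @export
population_heterozygosity <- function(pop) {
  stopifnot(inherits(pop, "population"))
  q <- colMeans(pop$geno) / 2
  mean(2 * q * (1 - q))
}

#' Found a population at Hardy-Weinberg proportions
#'
#' Builds the large "natural" population at the mutation-selection balance:
#' each individual's dosage at locus `l` is the sum of two independent
#' Bernoulli(`q_hat_l`) draws.
#'
#' @param genome A `genome_dfe` with `q_hat` set (0 is used where `q_hat`
#'   is `NA`, i.e. neutral loci of a selected genome).
#' @param n Census size (even).
#' @param seed RNG seed.
#' @return A [population()].
#' @export
found_natural_population <- function(genome, n, seed = NULL) {
  stopifnot(inherits(genome, "genome_dfe"))
  if (!is.null(seed)) set.seed(seed)
  q <- ifelse(is.na(genome$q_hat), 0, genome$q_hat)
  L <- nrow(genome)
  geno <- matrix(stats::rbinom(n * L, 2L, rep(q, each = n)), nrow = n)
  population(geno)
}

#' Advance a population by one generation
#'
#' One full cycle of the dioecious Wright-Fisher model: for each of `N`
#' offspring (exactly `N/2` per sex), a mother and a father are drawn
#' independently with replacement, with probability proportional to fitness
#' within their sex (polygamous mating); each parent transmits one allele
#' per locus by a fair Mendelian draw (loci unlinked); each transmitted
#' wild-type allele mutates to the deleterious allele with probability
#' `u_l`. With `selection = FALSE` parents are drawn uniformly (drift
#' only).
#'
#' @inheritParams genotype_fitness
#' @param selection Logical; apply fitness-proportional parent sampling.
#' @return The offspring [population()].
#' @export
next_generation <- function(pop, genome, selection = TRUE) {
  stopifnot(inherits(pop, "population"))
  g <- .genome_vecs(genome)
  res <- .wf_sim_cpp(pop$geno, pop$female, g$s, g$h, g$u, 1L, selection,
                     FALSE)
  population(res$geno, res$female)
}

#' Run the natural population / base population / derived line experiment
#'
#' Simulates the full experimental design: a large natural population at
#' mutation-selection balance is founded once from the genome's
#' equilibrium frequencies; for each replicate, `n_base` individuals are
#' sampled from it and maintained for `t_split` generations, a line of
#' `n_line` individuals is then sampled uniformly from the base population,
#' and both are maintained synchronously for a further `t_total`
#' generations. Mean fitness and the standing inbreeding load are recorded
#' every generation and averaged over replicates. A replicate in which one
#' sex loses all fitness goes extinct and is excluded (and counted).
#'
#' @param genome A `genome_dfe`.
#' @param n_base,n_line Census sizes of the base population and the line.
#' @param t_split Base generation at which the line is founded.
#' @param t_total Generations simulated after the split.
#' @param replicates Number of replicates to average.
#' @param seed RNG seed for the whole experiment (founding included).
#' @param selection Apply selection (`FALSE` gives the drift-only control).
#' @param n_natural Size of the natural founder pool.
#' @return An object of class `sim_result`: a data frame with columns
#'   `generation` (base-population scale), `pop` (`"base"`/`"line"`),
#'   `w_mean`, `w_sd`, `delta_mean`, `delta_sd`, `n_replicates`, plus
#'   attributes `n_extinct` and `config`.
#' @export
run_experiment <- function(genome, n_base, n_line, t_split, t_total,
                           replicates = 100, seed = NULL, selection = TRUE,
                           n_natural = 10000) {
  stopifnot(inherits(genome, "genome_dfe"),
            n_base %% 2 == 0, n_line %% 2 == 0,
            t_split >= 0, t_total >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- .genome_vecs(genome)
  natural <- found_natural_population(genome, n_natural)

  t_end <- t_split + t_total
  base_w <- base_d <- matrix(NA_real_, t_end + 1, replicates)
  line_w <- line_d <- matrix(NA_real_, t_total + 1, replicates)
  n_extinct <- 0L

  for (r in seq_len(replicates)) {
    ok <- tryCatch({
      founders <- sample.int(n_natural, n_base)
      base <- population(natural$geno[founders, , drop = FALSE])
      r1 <- .wf_sim_cpp(base$geno, base$female, g$s, g$h, g$u,
                        as.integer(t_split), selection, FALSE)
      line_rows <- sample.int(n_base, n_line)
      line <- population(r1$geno[sort(line_rows), , drop = FALSE])
      r2 <- .wf_sim_cpp(r1$geno, r1$female, g$s, g$h, g$u,
                        as.integer(t_total), selection, FALSE)
      r3 <- .wf_sim_cpp(line$geno, line$female, g$s, g$h, g$u,
                        as.integer(t_total), selection, FALSE)
      base_w[, r] <- c(r1$w_mean, r2$w_mean[-1])
      base_d[, r] <- c(r1$load, r2$load[-1])
      line_w[, r] <- r3$w_mean
      line_d[, r] <- r3$load
      TRUE
    }, error = function(e) {
      if (grepl("extinction", conditionMessage(e))) FALSE else stop(e)
    })
    if (!ok) n_extinct <- n_extinct + 1L
  }

  used_b <- colSums(is.na(base_w)) == 0
  used_l <- colSums(is.na(line_w)) == 0
  if (!any(used_b)) stop("all replicates went extinct")
  summ <- function(m, used) {
    m <- m[, used, drop = FALSE]
    list(mean = rowMeans(m), sd = apply(m, 1, stats::sd))
  }
  sb_w <- summ(base_w, used_b); sb_d <- summ(base_d, used_b)
  sl_w <- summ(line_w, used_l); sl_d <- summ(line_d, used_l)

  out <- rbind(
    data.frame(generation = 0:t_end, pop = "base",
               w_mean = sb_w$mean, w_sd = sb_w$sd,
               delta_mean = sb_d$mean, delta_sd = sb_d$sd,
               n_replicates = sum(used_b)),
    data.frame(generation = t_split + 0:t_total, pop = "line",
               w_mean = sl_w$mean, w_sd = sl_w$sd,
               delta_mean = sl_d$mean, delta_sd = sl_d$sd,
               n_replicates = sum(used_l))
  )
  class(out) <- c("sim_result", "data.frame")
  attr(out, "n_extinct") <- n_extinct
  attr(out, "config") <- list(n_base = n_base, n_line = n_line,
                              t_split = t_split, t_total = t_total,
                              replicates = replicates, seed = seed,
                              selection = selection,
                              n_natural = n_natural)
  out
}

#' Mean-square fit between simulated and observed load trajectories
#'
#' Quality of fit of a simulation to observed inbreeding-load estimates:
#' the mean over all observed points (base population and line pooled) of
#' the squared difference between the observed load and the
#' replicate-averaged simulated load at the same generation.
#'
#' @param sim A `sim_result` from [run_experiment()].
#' @param observed Data frame with columns `generation` (base-population
#'   scale), `pop` (`"base"`/`"line"`) and `delta`.
#' @return The mean squared difference.
#' @export
fit_quality <- function(sim, observed) {
  stopifnot(inherits(sim, "sim_result"),
            all(c("generation", "pop", "delta") %in% names(observed)))
  sq <- mapply(function(gen, pp, dl) {
    row <- sim$generation == gen & sim$pop == pp
    if (!any(row)) stop("observed generation ", gen,
                        " (", pp, ") outside the simulated range")
    (dl - sim$delta_mean[row][1])^2
  }, observed$generation, observed$pop, observed$delta)
  mean(sq)
}
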