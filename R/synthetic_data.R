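#' Configuration for synthetic productivity assays
#'
#' Describes a synthetic version of the paired noninbred/inbred full-sib
#' productivity design with a known true inbreeding load. Outbred pair
#' counts are drawn with mean `p0`; inbred pair counts with mean
#' `p0 * exp(-delta_true * F_bar)`, where `F_bar` is the average of the
#' inbred parental and progeny inbreeding coefficients -- exactly the
#' signal the lethal-equivalents estimator assumes, so recovery tests are
#' well-posed. Counts are negative binomial (Poisson fecundity mixed with
#' gamma heterogeneity across pairs); the default `dispersion` (size)
#' parameter of 20 reproduces the coefficient of variation of roughly 0.25
#' implied by the published productivity means and standard errors.
#'
#' @param delta_true Generating inbreeding load (lethal equivalents).
#' @param p0 Outbred mean productivity (pupae per pair, > 0).
#' @param f_parents,f_offspring Inbred-scheme inbreeding coefficients.
#' @param n_out,n_in Number of pairs per scheme.
#' @param dispersion Negative-binomial size parameter (> 0); larger values
#'   approach Poisson noise.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(delta_true, p0 = 87, f_parents = 0.25,
                         f_offspring = 0.375, n_out = 200, n_in = 200,
                         dispersion = 20, seed = NULL) {
  stopifnot(p0 > 0, dispersion > 0, n_out >= 1, n_in >= 1,
            f_parents >= 0, f_parents <= 1,
            f_offspring >= 0, f_offspring <= 1)
  structure(list(delta_true = delta_true, p0 = p0, f_parents = f_parents,
                 f_offspring = f_offspring, n_out = n_out, n_in = n_in,
                 dispersion = dispersion, seed = seed),
            class = "synth_config")
}

#' Generate one synthetic outbred/inbred assay pair
#'
#' @param config A [synth_config()].
#' @return List with elements `outbred` and `inbred`
#'   ([productivity_assay()] objects).
#' @examples
#' a <- generate_assay_pair(synth_config(0.85, seed = 1))
#' estimate_delta(a$outbred, a$inbred)
#' @export
generate_assay_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  f_bar <- mean_inbreeding_coefficient(config$f_parents, config$f_offspring)
  mu_in <- config$p0 * exp(-config$delta_true * f_bar)
  out <- stats::rnbinom(config$n_out, size = config$dispersion,
                        mu = config$p0)
  inb <- stats::rnbinom(config$n_in, size = config$dispersion, mu = mu_in)
  list(outbred = productivity_assay(out, "outbred"),
       inbred = productivity_assay(inb, "inbred",
                                   f_parents = config$f_parents,
                                   f_offspring = config$f_offspring))
}

#' Generate a multi-generation synthetic assay table
#'
#' Builds a full pair-level assay table (one row per mated pair, assay CSV
#' schema) for a schedule of surveyed generations with known true loads,
#' e.g. a load trajectory produced by the IP model. Suitable for
#' end-to-end tests: estimate the load per generation, then fit the
#' purging coefficient and compare against the generating value.
#'
#' @param schedule Data frame with columns `generation` and `delta_true`
#'   (one row per surveyed generation); an optional `population` column is
#'   carried through (default `"synthetic"`).
#' @param p0 Outbred mean productivity, recycled over generations (a
#'   vector allows environmental drift of the common mean).
#' @param f_parents,f_offspring Inbred-scheme coefficients.
#' @param n_out,n_in Pairs per scheme and generation.
#' @param dispersion Negative-binomial size parameter.
#' @param seed RNG seed; the table is deterministic given the seed.
#' @return Data frame in the assay schema: `population, generation,
#'   scheme, F_parents, F_offspring, pair_id, pupae_count`.
#' @export
generate_experiment_table <- function(schedule, p0 = 87, f_parents = 0.25,
                                      f_offspring = 0.375, n_out = 200,
                                      n_in = 200, dispersion = 20,
                                      seed = NULL) {
  stopifnot(all(c("generation", "delta_true") %in% names(schedule)))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(schedule) == 0) {
    return(data.frame(population = character(), generation = numeric(),
                      scheme = character(), F_parents = numeric(),
                      F_offspring = numeric(), pair_id = integer(),
                      pupae_count = numeric()))
  }
  popname <- if ("population" %in% names(schedule)) {
    schedule$population
  } else {
    rep("synthetic", nrow(schedule))
  }
  p0 <- rep_len(p0, nrow(schedule))
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    cfg <- synth_config(schedule$delta_true[i], p0 = p0[i],
                        f_parents = f_parents, f_offspring = f_offspring,
                        n_out = n_out, n_in = n_in,
                        dispersion = dispersion, seed = NULL)
    pair <- generate_assay_pair(cfg)
    data.frame(
      population = popname[i],
      generation = schedule$generation[i],
      scheme = c(rep("outbred", n_out), rep("inbred", n_in)),
      F_parents = c(rep(0, n_out), rep(f_parents, n_in)),
      F_offspring = c(rep(0, n_out), rep(f_offspring, n_in)),
      pair_id = c(seq_len(n_out), seq_len(n_in)),
      pupae_count = c(pair$outbred$counts, pair$inbred$counts)
    )
  })
  do.call(rbind, rows)
}

#' Estimate loads for every stratum of an assay table
#'
#' Convenience wrapper running [bootstrap_load()] on each
#' population-by-generation stratum of a pair-level assay table.
#'
#' @param table Data frame in the assay schema (see [read_assay_table()]).
#' @param B Bootstrap replicates per stratum.
#' @param seed Base RNG seed; stratum `i` uses `seed + i - 1`.
#' @return Data frame with one row per stratum: `population, generation,
#'   n_out, n_in, p_out, p_in, f_bar, delta, se, p_leq_zero`.
#' @export
estimate_load_table <- function(table, B = 1000, seed = NULL) {
  strata <- unique(table[, c("population", "generation")])
  strata <- strata[order(strata$population, strata$generation), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sub <- table[table$population == strata$population[i] &
                   table$generation == strata$generation[i], ,
                 drop = FALSE]
    assays <- assays_from_table(sub)
    est <- bootstrap_load(assays$outbred, assays$inbred, B = B,
                          seed = if (is.null(seed)) NULL else seed + i - 1)
    data.frame(
      population = strata$population[i],
      generation = strata$generation[i],
      n_out = assays$outbred$n, n_in = assays$inbred$n,
      p_out = mean(assays$outbred$counts),
      p_in = mean(assays$inbred$counts),
      f_bar = mean_inbreeding_coefficient(assays$inbred$f_parents,
                                          assays$inbred$f_offspring),
      delta = est$delta, se = est$se, p_leq_zero = est$p_leq_zero
    )
  })
  do.call(rbind, rows)
}
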