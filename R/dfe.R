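#' Deleterious-mutation model (distribution of fitness effects)
#'
#' Specifies how homozygous selection coefficients `s`, dominance
#' coefficients `h` and mutation rates are assigned to the `L` diploid
#' genomic positions of a simulated genome.
#'
#' Families:
#' * `"gamma_uniform_h"`: `s ~ Gamma(shape = beta, mean = s_mean)` with
#'   values above 1 redefined as `s = 1` (the lethal class), and
#'   `h | s ~ Uniform(0, exp(-k s))` with `k` solved so that the mean
#'   dominance over the truncated `s` distribution equals `h_mean`.
#' * `"kim_piecewise_h"`: the genomic-inference model with
#'   `s_mean = 0.0161`, `beta = 0.186` and a piecewise constant dominance
#'   `h = 0.25` for `s < 0.02`, `h = 0` otherwise.
#' * `"neutral"`: `s = h = 0` everywhere (drift-only control).
#'
#' `U` is the haploid genomic mutation rate per generation; each locus
#' mutates wild-type -> deleterious at `u = U / L`.
#'
#' @param family Model family (see above).
#' @param s_mean Mean homozygous selection coefficient (before truncation).
#' @param beta Gamma shape parameter.
#' @param h_mean Target mean dominance coefficient (gamma_uniform_h only),
#'   in `(0, 0.5)`; `k` is solved at construction.
#' @param U Haploid genomic mutation rate per generation.
#' @param L Number of diploid genomic positions.
#' @return An object of class `dfe_model` (fields include the solved `k`
#'   for gamma_uniform_h).
#' @examples
#' dfe_model("gamma_uniform_h", s_mean = 0.3, h_mean = 0.25, U = 0.02)
#' @export
dfe_model <- function(family = c("gamma_uniform_h", "kim_piecewise_h",
                                 "neutral"),
                      s_mean = NULL, beta = 0.2, h_mean = NULL,
                      U = 0.02, L = 9000L) {
  family <- match.arg(family)
  stopifnot(U > 0, L >= 1, L == round(L))
  k <- NA_real_
  if (family == "gamma_uniform_h") {
    stopifnot(!is.null(s_mean), s_mean > 0, beta > 0,
              !is.null(h_mean), h_mean > 0)
    if (h_mean >= 0.5) stop("h_mean must be below 0.5 (k would be negative)")
    k <- solve_k(s_mean, beta, h_mean)
  } else if (family == "kim_piecewise_h") {
    s_mean <- 0.0161
    beta <- 0.186
    h_mean <- NA_real_
  } else {
    s_mean <- 0
    beta <- NA_real_
    h_mean <- NA_real_
  }
  structure(list(family = family, s_mean = s_mean, beta = beta,
                 h_mean = h_mean, k = k, U = U, L = as.integer(L),
                 u = U / L),
            class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat(sprintf("DFE model '%s': s_mean = %g, beta = %g, h_mean = %g, k = %g, U = %g, L = %d\n",
              x$family, x$s_mean, x$beta, x$h_mean, x$k, x$U, x$L))
  invisible(x)
}

#' Mean of exp(-k s) over the truncated gamma effect distribution
#'
#' Expectation over `s ~ Gamma(shape = beta, mean = s_mean)` truncated at 1
#' (the probability mass above 1 sits as a point mass at `s = 1`): the
#' continuous part is integrated by adaptive quadrature and the lethal mass
#' contributes `exp(-k)`. Internal helper for [solve_k()].
#' @keywords internal
.mean_exp_ks <- function(k, s_mean, beta) {
  scale <- s_mean / beta
  cont <- stats::integrate(function(s) exp(-k * s) *
                             stats::dgamma(s, shape = beta, scale = scale),
                           0, 1, rel.tol = 1e-11, abs.tol = 1e-12)$value
  cont + exp(-k) *
    stats::pgamma(1, shape = beta, scale = scale, lower.tail = FALSE)
}

#' Solve the dominance-decay constant k
#'
#' Under the `gamma_uniform_h` family, `h | s ~ Uniform(0, exp(-k s))` so
#' the mean dominance is `E[exp(-k s)] / 2` over the truncated effect
#' distribution. `solve_k()` finds the `k >= 0` that makes this equal
#' `h_mean`, by root bracketing on the quadrature described above to an
#' absolute tolerance of `1e-8` in the expectation.
#'
#' @param s_mean,beta Gamma mean and shape of the effect distribution.
#' @param h_mean Target mean dominance coefficient in `(0, 0.5]`.
#' @return The constant `k >= 0` (`k = 0` when `h_mean = 0.5`).
#' @examples
#' solve_k(0.3, 0.2, 0.25)
#' @export
solve_k <- function(s_mean, beta, h_mean) {
  stopifnot(s_mean > 0, beta > 0, h_mean > 0)
  if (h_mean > 0.5) stop("h_mean above 0.5 is infeasible under this family")
  if (h_mean == 0.5) return(0)
  f <- function(k) .mean_exp_ks(k, s_mean, beta) - 2 * h_mean
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Sample a deleterious-mutation genome
#'
#' Draws per-locus selection and dominance coefficients for all `L`
#' positions of a [dfe_model()], truncating sampled `s > 1` to the lethal
#' class `s = 1` before dominance assignment, and solves the deterministic
#' mutation-selection-balance frequency and load at every selected locus.
#'
#' @param model A [dfe_model()].
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A `genome_dfe`: data frame with columns `s`, `h`, `u`, `q_hat`,
#'   `load` (one row per locus) and the model and seed in attributes.
#' @examples
#' g <- sample_dfe(dfe_model("gamma_uniform_h", s_mean = 0.2, h_mean = 0.25,
#'                           U = 0.02, L = 2000), seed = 1)
#' genome_load(g)
#' @export
sample_dfe <- function(model, seed = NULL) {
  stopifnot(inherits(model, "dfe_model"))
  if (!is.null(seed)) set.seed(seed)
  L <- model$L
  if (model$family == "neutral") {
    s <- rep(0, L)
    h <- rep(0, L)
  } else {
    s <- stats::rgamma(L, shape = model$beta,
                       scale = model$s_mean / model$beta)
    s[s > 1] <- 1
    h <- if (model$family == "gamma_uniform_h") {
      stats::runif(L, 0, exp(-model$k * s))
    } else {
      ifelse(s < 0.02, 0.25, 0)
    }
  }
  q <- rep(NA_real_, L)
  sel <- s > 0
  q[sel] <- equilibrium_frequency(s[sel], h[sel], model$u)
  load <- ifelse(sel, locus_load(s, h, ifelse(sel, q, 0)), 0)
  out <- data.frame(s = s, h = h, u = rep(model$u, L), q_hat = q,
                    load = load)
  class(out) <- c("genome_dfe", "data.frame")
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Construct a genome from explicit per-locus parameters
#'
#' Builds a `genome_dfe` directly from vectors of `s`, `h`, `u` and allele
#' frequencies, bypassing the sampling families. Used for controlled test
#' genomes (e.g. a drift-only genome seeded with a known load).
#'
#' @param s,h Per-locus homozygous effect and dominance coefficient.
#' @param u Per-locus mutation rate (recycled).
#' @param q_hat Per-locus initial/equilibrium mutant frequency.
#' @return A `genome_dfe` data frame.
#' @export
genome_manual <- function(s, h, u = 0, q_hat = 0) {
  n <- max(length(s), length(h))
  out <- data.frame(s = rep_len(s, n), h = rep_len(h, n),
                    u = rep_len(u, n), q_hat = rep_len(q_hat, n))
  out$load <- locus_load(out$s, out$h, out$q_hat)
  class(out) <- c("genome_dfe", "data.frame")
  out
}

#' Mutation-selection-balance equilibrium frequency
#'
#' Deterministic equilibrium frequency `q_hat` of a deleterious allele under
#' one-way mutation (rate `u`), selection (`s`, `h`) and random mating. The
#' single-generation recurrence for the wild-type frequency,
#' `p' = [p^2 + p q (1 - s h)] (1 - u) / [1 - 2 p q s h - q^2 s]`,
#' reduces algebraically at its fixed point to the quadratic
#' `s (2h - 1) q^2 - s h (1 + u) q + u = 0`, which is solved in its
#' numerically stable form. When no interior fixed point exists (selection
#' weaker than mutation pressure) the equilibrium is fixation, `q_hat = 1`.
#' Classical limits: `q_hat -> sqrt(u/s)` for `h = 0` and `q_hat -> u/(sh)`
#' for `sh >> u`.
#'
#' @param s Homozygous selection coefficient(s), in `(0, 1]`.
#' @param h Dominance coefficient(s), in `[0, 1]`.
#' @param u Per-locus mutation rate, in `(0, 1)`.
#' @return Equilibrium mutant frequency (vectorised over loci); every
#'   returned interior value satisfies the recurrence to `<= 1e-10`.
#' @examples
#' equilibrium_frequency(1, 0, 1e-5)     # ~ sqrt(u/s)
#' equilibrium_frequency(0.1, 0.25, 1e-5)  # ~ u/(sh)
#' @export
equilibrium_frequency <- function(s, h, u) {
  if (any(s <= 0)) stop("neutral loci (s = 0) have no selection balance")
  stopifnot(all(s <= 1), all(h >= 0), all(h <= 1), all(u > 0), all(u < 1))
  n <- max(length(s), length(h), length(u))
  s <- rep_len(s, n); h <- rep_len(h, n); u <- rep_len(u, n)
  a <- s * (2 * h - 1)
  b <- -s * h * (1 + u)
  cc <- u
  disc <- b^2 - 4 * a * cc
  # small root of the quadratic, stable when a -> 0 (h -> 1/2)
  q <- ifelse(disc < 0, 1, 2 * cc / (-b + sqrt(pmax(disc, 0))))
  pmin(q, 1)
}

#' Fixed-point residual of the equilibrium recurrence
#'
#' One-generation displacement `q' - q` of the mutation-selection recurrence
#' evaluated at `q`; zero (to numerical tolerance) at an equilibrium.
#' Exposed for verification of [equilibrium_frequency()].
#'
#' @inheritParams equilibrium_frequency
#' @param q Allele frequency at which to evaluate the recurrence.
#' @return `q' - q` after one generation of selection then mutation.
#' @export
msb_residual <- function(q, s, h, u) {
  p <- 1 - q
  wbar <- 1 - 2 * p * q * s * h - q^2 * s
  p_next <- (p^2 + p * q * (1 - s * h)) * (1 - u) / wbar
  (1 - p_next) - q
}

#' Per-locus inbreeding-load contribution
#'
#' Morton-style load contribution of one locus,
#' `delta = s (1 - 2h) p q` with `p = 1 - q`: the concealed recessive
#' component that inbreeding would expose. Zero at additivity (`h = 0.5`)
#' and at fixation.
#'
#' @inheritParams equilibrium_frequency
#' @param q Mutant allele frequency in `[0, 1]`.
#' @return Load contribution(s) in lethal equivalents.
#' @export
locus_load <- function(s, h, q) {
  stopifnot(all(q >= 0), all(q <= 1))
  s * (1 - 2 * h) * (1 - q) * q
}

#' Total inbreeding load of a genome
#'
#' Sum of the per-locus load contributions `s (1 - 2h) p q` over all loci.
#'
#' @param genome A `genome_dfe` from [sample_dfe()] or [genome_manual()].
#' @return Total inbreeding load (lethal equivalents).
#' @export
genome_load <- function(genome) {
  stopifnot(inherits(genome, "genome_dfe"))
  sum(genome$load)
}

#' Share of the inbreeding load from small-effect loci
#'
#' Fraction of the total equilibrium inbreeding load contributed by loci
#' whose homozygous effect is below `s_cut`. Quantifies how much of the
#' concealed load would need slow inbreeding to be purged (small `s` means
#' weak selection against homozygotes).
#'
#' @param genome A `genome_dfe` with computed loads.
#' @param s_cut Effect-size threshold.
#' @return Fraction in `[0, 1]`.
#' @export
load_fraction_below <- function(genome, s_cut) {
  stopifnot(inherits(genome, "genome_dfe"))
  total <- sum(genome$load)
  if (total <= 0) stop("total load is zero: fraction undefined")
  sum(genome$load[genome$s < s_cut]) / total
}

#' Calibrate the genomic mutation rate to a target inbreeding load
#'
#' Adjusts the haploid genomic mutation rate `U` so that the deterministic
#' equilibrium genome carries a prescribed total inbreeding load,
#' mirroring how simulated populations are matched to the load inferred in
#' the experimental populations. The per-locus draw of `(s, h)` is held
#' fixed (same seed) while `U` varies, so the reported `U` is conditional
#' on that genome realisation; equilibrium frequencies are re-solved at
#' `u = U / L` for every candidate `U`.
#'
#' @param model A [dfe_model()]; its `U` field is ignored.
#' @param target_load Desired total load (> 0), in lethal equivalents.
#' @param seed Seed of the locus draw.
#' @param bounds Search interval for `U`.
#' @param tol Absolute tolerance on the achieved load.
#' @return A list with `U` (calibrated rate), `load` (achieved), and
#'   `genome` (the calibrated `genome_dfe`).
#' @examples
#' m <- dfe_model("kim_piecewise_h", L = 9000)
#' calibrate_mutation_rate(m, target_load = 2, seed = 1)$U  # ~ 0.16
#' @export
calibrate_mutation_rate <- function(model, target_load, seed = NULL,
                                    bounds = c(1e-4, 2), tol = 1e-3) {
  stopifnot(inherits(model, "dfe_model"), target_load > 0)
  if (model$family == "neutral") stop("a neutral genome carries no load")
  base <- sample_dfe(model, seed = seed)  # fixes the (s, h) draw
  sel <- base$s > 0
  load_at <- function(U) {
    q <- equilibrium_frequency(base$s[sel], base$h[sel], U / model$L)
    sum(locus_load(base$s[sel], base$h[sel], q))
  }
  lo <- load_at(bounds[1]); hi <- load_at(bounds[2])
  if (target_load < lo || target_load > hi) {
    stop(sprintf("target load %.3g unreachable within U bounds [%g, %g] (load range %.3g-%.3g)",
                 target_load, bounds[1], bounds[2], lo, hi))
  }
  root <- stats::uniroot(function(U) load_at(U) - target_load, bounds,
                         tol = .Machine$double.eps^0.5)
  U <- root$root
  achieved <- load_at(U)
  if (abs(achieved - target_load) > tol) {
    stop("calibration did not reach the target load within tolerance")
  }
  genome <- base
  genome$u <- rep(U / model$L, nrow(genome))
  genome$q_hat[sel] <- equilibrium_frequency(base$s[sel], base$h[sel],
                                             U / model$L)
  genome$load <- ifelse(sel,
                        locus_load(genome$s, genome$h,
                                   ifelse(sel, genome$q_hat, 0)), 0)
  mod <- attr(genome, "model"); mod$U <- U; mod$u <- U / model$L
  attr(genome, "model") <- mod
  list(U = U, load = achieved, genome = genome)
}
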