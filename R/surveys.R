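#' Summary data from the long-term Drosophila slow-inbreeding experiments
#'
#' Published summary statistics of the two long-term *Drosophila
#' melanogaster* slow-inbreeding experiments the package analyses: a large
#' base population (Madrid, `Ne ~ 1376`; Vigo, `Ne ~ 1000`) maintained for
#' up to 234 generations, and derived lines of effective size about 43
#' (Madrid) and 52 (Vigo) split from them at base generations 83 and 86.
#' At each surveyed generation, pupae productivity was assayed in a
#' noninbred scheme (`P_O`, crosses between unrelated vials) and an inbred
#' scheme (`P_I`, full-sib matings giving parents `F = 0.25` and progeny
#' `F = 0.375` in most surveys), from which the inbreeding load
#' `delta = ln(P_O/P_I)/F` was estimated.
#'
#' Only surveys with both schemes reported are included. Line generations
#' carry the synchronous base-population generation in `gen_base`.
#'
#' @return A data frame with columns `population` (`"madrid"`/`"vigo"`),
#'   `cohort` (`"base"`/`"line"`), `generation`, `gen_base`, `f_mother`,
#'   `f_offspring`, `n_out`, `p_out`, `se_out`, `n_in`, `p_in`, `se_in`,
#'   `delta`, `se_delta` (reported load and bootstrap standard error).
#' @examples
#' s <- load_survey()
#' with(s[1, ], delta_from_means(p_out, p_in,
#'   mean_inbreeding_coefficient(f_mother, f_offspring)))
#' @export
load_survey <- function() {
  data.frame(
    population = c(rep("madrid", 5), rep("vigo", 7)),
    cohort = c("base", "base", "base", "line", "line",
               "base", "base", "base", "base", "base", "line", "line"),
    generation = c(112, 201, 234, 120, 153,
                   22, 50, 103, 111, 125, 25, 39),
    gen_base = c(112, 201, 234, 201, 234,
                 22, 50, 103, 111, 125, 111, 125),
    f_mother = c(0.25, 0.25, 0.25, 0.25, 0.25,
                 0.375, 0.25, 0.375, 0.25, 0.25, 0.25, 0.25),
    f_offspring = c(0.25, 0.375, 0.375, 0.375, 0.375,
                    0.5, 0.375, 0.5, 0.375, 0.375, 0.375, 0.375),
    n_out = c(108, 210, 215, 337, 335, 71, 147, 22, 227, 388, 239, 283),
    p_out = c(86.91, 94.99, 86.96, 81.84, 72.04,
              101.97, 45.94, 95.32, 87.30, 64.35, 89.49, 58.35),
    se_out = c(2.12, 1.12, 1.40, 1.25, 1.46,
               2.38, 1.01, 4.39, 2.08, 0.70, 1.66, 0.79),
    n_in = c(200, 184, 144, 339, 323, 99, 145, 53, 251, 252, 230, 315),
    p_in = c(70.30, 90.60, 83.11, 78.30, 71.72,
             47.56, 29.71, 71.24, 72.16, 62.08, 71.28, 59.19),
    se_in = c(1.79, 1.67, 2.21, 1.43, 1.41,
              2.11, 0.96, 5.33, 1.83, 1.18, 2.05, 0.89),
    delta = c(0.848, 0.151, 0.145, 0.141, 0.014,
              1.744, 1.395, 0.666, 0.609, 0.115, 0.728, -0.046),
    se_delta = c(0.142, 0.070, 0.098, 0.075, 0.083,
                 0.112, 0.136, 0.188, 0.109, 0.069, 0.111, 0.063),
    stringsAsFactors = FALSE
  )
}

#' Reference IP parameters for the experimental populations
#'
#' The effective sizes, initial inbreeding loads (inferred under the IP
#' model at the founding of each cohort) and the globally estimated purging
#' coefficient `d = 0.3` for the four experimental cohorts. Line loads are
#' the IP-inferred loads at the generation the lines were split from their
#' base population (base generation 83 for Madrid, 86 for Vigo).
#'
#' @param population `"madrid"` or `"vigo"`.
#' @param cohort `"base"` or `"line"`.
#' @param d Purging coefficient to embed (default the global estimate 0.3).
#' @return An [ip_params()] object.
#' @examples
#' ip_reference_params("madrid", "line")
#' @export
ip_reference_params <- function(population = c("madrid", "vigo"),
                                cohort = c("base", "line"), d = 0.3) {
  population <- match.arg(population)
  cohort <- match.arg(cohort)
  ne <- switch(population,
               madrid = c(base = 1376, line = 43),
               vigo = c(base = 1000, line = 52))[[cohort]]
  delta0 <- switch(population,
                   madrid = c(base = 2.0, line = 1.402),
                   vigo = c(base = 1.85, line = 0.92))[[cohort]]
  ip_params(ne = ne, d = d, delta0 = delta0)
}

#' Generation at which the derived lines were split from their base
#'
#' @param population `"madrid"` or `"vigo"`.
#' @return Base-population generation of the split (83 or 86).
#' @export
line_split_generation <- function(population = c("madrid", "vigo")) {
  switch(match.arg(population), madrid = 83L, vigo = 86L)
}
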