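#' Pair-level productivity assay
#'
#' Container for one evaluation scheme of the paired productivity design:
#' either the noninbred scheme (crosses between unrelated vials, parents and
#' offspring noninbred) or the inbred scheme (full-sib matings, so parents
#' and offspring carry known expected inbreeding coefficients). Holds the
#' per-pair pupae counts on which the bootstrap resamples.
#'
#' @param counts Non-negative integer pupae counts, one per mated pair.
#' @param scheme `"outbred"` or `"inbred"`.
#' @param f_parents,f_offspring Expected inbreeding coefficients of the
#'   mated pair and of their progeny. Must both be 0 for the outbred scheme.
#' @return An object of class `productivity_assay`.
#' @examples
#' productivity_assay(c(80, 95, 72), "inbred",
#'                    f_parents = 0.25, f_offspring = 0.375)
#' @export
productivity_assay <- function(counts, scheme = c("outbred", "inbred"),
                               f_parents = 0, f_offspring = 0) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(counts), length(counts) >= 1, all(counts >= 0))
  stopifnot(f_parents >= 0, f_parents <= 1, f_offspring >= 0, f_offspring <= 1)
  if (scheme == "outbred" && (f_parents != 0 || f_offspring != 0)) {
    stop("the outbred scheme must have F_parents = F_offspring = 0")
  }
  structure(list(counts = as.numeric(counts), scheme = scheme,
                 f_parents = f_parents, f_offspring = f_offspring,
                 n = length(counts)),
            class = "productivity_assay")
}

#' @export
print.productivity_assay <- function(x, ...) {
  cat(sprintf("%s assay: n = %d pairs, mean productivity %.2f (F %g/%g)\n",
              x$scheme, x$n, mean(x$counts), x$f_parents, x$f_offspring))
  invisible(x)
}

#' Average inbreeding coefficient of parents and progeny
#'
#' Productivity depends on both the parental genotypes (mating success,
#' fecundity) and the progeny genotypes (survival to pupation), so the load
#' estimator divides by the arithmetic mean of the two coefficients.
#'
#' @param f_parents,f_offspring Inbreeding coefficients in `[0, 1]`.
#' @return Their arithmetic mean.
#' @examples
#' mean_inbreeding_coefficient(0.25, 0.375)  # the standard full-sib design
#' @export
mean_inbreeding_coefficient <- function(f_parents, f_offspring) {
  stopifnot(all(f_parents >= 0 & f_parents <= 1),
            all(f_offspring >= 0 & f_offspring <= 1))
  (f_parents + f_offspring) / 2
}

#' Inbreeding load from scheme means (lethal equivalents)
#'
#' The point estimator `delta = ln(P_O / P_I) / F`, where `P_O` and `P_I`
#' are the mean productivities of the noninbred and inbred schemes and `F`
#' the average inbreeding coefficient of inbred parents and progeny.
#'
#' @param p_out,p_in Mean productivity of the outbred / inbred scheme (> 0).
#' @param f_bar Average inbreeding coefficient of the inbred scheme (> 0).
#' @return The inbreeding load in lethal equivalents (sign free).
#' @examples
#' delta_from_means(86.91, 70.30, 0.25)
#' @export
delta_from_means <- function(p_out, p_in, f_bar) {
  if (any(p_out <= 0) || any(p_in <= 0)) {
    stop("undefined load: scheme mean productivity must be positive")
  }
  if (any(f_bar <= 0)) stop("mean inbreeding coefficient must be positive")
  log(p_out / p_in) / f_bar
}

#' Inbreeding load from a pair of assays
#'
#' Applies [delta_from_means()] to the per-pair means of an outbred and an
#' inbred [productivity_assay()]. The denominator `F` always comes from the
#' inbred scheme's parental and progeny coefficients; the outbred scheme is
#' validated to be noninbred but contributes only its mean.
#'
#' @param outbred,inbred [productivity_assay()] objects of the matching
#'   schemes.
#' @return The inbreeding load in lethal equivalents.
#' @export
estimate_delta <- function(outbred, inbred) {
  stopifnot(inherits(outbred, "productivity_assay"),
            inherits(inbred, "productivity_assay"))
  if (outbred$scheme != "outbred" || inbred$scheme != "inbred") {
    stop("arguments must be an outbred and an inbred assay, in that order")
  }
  f_bar <- mean_inbreeding_coefficient(inbred$f_parents, inbred$f_offspring)
  delta_from_means(mean(outbred$counts), mean(inbred$counts), f_bar)
}

#' Bootstrap inference for the inbreeding load
#'
#' Resamples pairs with replacement, independently within the outbred and
#' inbred schemes (the design has no pairing across schemes), recomputing
#' the load for each of `B` replicates. The standard error is the standard
#' deviation of the replicate loads and `p_leq_zero` is the one-sided
#' bootstrap probability that the load is at or below zero. A replicate in
#' which either scheme resamples to a zero mean (possible only when zero
#' counts are present) is redrawn so that `B` valid replicates are always
#' obtained; the number of redraws is reported.
#'
#' @inheritParams estimate_delta
#' @param B Number of bootstrap replicates.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return An object of class `load_estimate`: list with `delta`, `se`,
#'   `p_leq_zero`, `replicates` (the B bootstrap loads), `B`, `seed`,
#'   `n_redrawn`.
#' @examples
#' out <- productivity_assay(rpois(50, 85), "outbred")
#' inb <- productivity_assay(rpois(50, 70), "inbred", 0.25, 0.375)
#' bootstrap_load(out, inb, B = 200, seed = 1)
#' @export
bootstrap_load <- function(outbred, inbred, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  delta <- estimate_delta(outbred, inbred)
  f_bar <- mean_inbreeding_coefficient(inbred$f_parents, inbred$f_offspring)
  if (!is.null(seed)) set.seed(seed)
  reps <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      m_out <- mean(sample(outbred$counts, outbred$n, replace = TRUE))
      m_in <- mean(sample(inbred$counts, inbred$n, replace = TRUE))
      if (m_out > 0 && m_in > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    reps[b] <- log(m_out / m_in) / f_bar
  }
  structure(list(delta = delta, se = stats::sd(reps),
                 p_leq_zero = mean(reps <= 0), replicates = reps,
                 B = B, seed = seed, n_redrawn = n_redrawn),
            class = "load_estimate")
}

#' @export
print.load_estimate <- function(x, ...) {
  cat(sprintf("inbreeding load: delta = %.3f +/- %.3f (B = %d, p[delta<=0] = %.3f)\n",
              x$delta, x$se, x$B, x$p_leq_zero))
  invisible(x)
}

.boot_reps <- function(x) {
  if (inherits(x, "load_estimate")) x$replicates else as.numeric(x)
}

#' Bootstrap comparison of two load estimates
#'
#' One-sided bootstrap p-value for the difference between two loads: the
#' replicate series of the larger point estimate is labelled `a`, replicates
#' are paired by index (the schemes underlying the two estimates are
#' independent, so index pairing is an arbitrary but valid coupling), and
#' `p` is the fraction of differences `a* - b* <= 0`. If the series differ
#' in length the shorter one is resampled with replacement to match.
#'
#' @param a,b `load_estimate` objects or numeric bootstrap replicate series.
#' @return One-sided p-value for equality of the two loads.
#' @export
compare_loads <- function(a, b) {
  ra <- .boot_reps(a); rb <- .boot_reps(b)
  stopifnot(length(ra) >= 1, length(rb) >= 1)
  if (mean(ra) < mean(rb)) { tmp <- ra; ra <- rb; rb <- tmp }
  if (length(ra) != length(rb)) {
    n <- max(length(ra), length(rb))
    if (length(ra) < n) ra <- sample(ra, n, replace = TRUE)
    if (length(rb) < n) rb <- sample(rb, n, replace = TRUE)
  }
  mean(ra - rb <= 0)
}

#' Bootstrap test of an observed load against a model prediction
#'
#' One-sided bootstrap p-value that the observed load is compatible with a
#' theoretical prediction: the fraction of bootstrap replicates at or beyond
#' the predicted value on the side opposite the observed deviation. If the
#' point estimate exceeds the prediction, `p` is the fraction of replicates
#' `<=` the prediction, and vice versa.
#'
#' @param replicates A `load_estimate` or numeric bootstrap replicate series.
#' @param predicted The model-predicted load.
#' @return One-sided p-value.
#' @export
test_against_prediction <- function(replicates, predicted) {
  r <- .boot_reps(replicates)
  stopifnot(length(r) >= 1, is.finite(predicted))
  if (mean(r) >= predicted) mean(r <= predicted) else mean(r >= predicted)
}

#' Read / write pair-level assay tables
#'
#' The assay table format is a plain CSV with one row per mated pair and
#' columns `population, generation, scheme, F_parents, F_offspring, pair_id,
#' pupae_count`. [read_assay_table()] validates the schema;
#' [assays_from_table()] splits one population/generation stratum into the
#' outbred/inbred [productivity_assay()] pair used by the estimators.
#'
#' @param path File path.
#' @param table A data frame in the assay schema.
#' @return `read_assay_table()`: the validated data frame.
#'   `assays_from_table()`: list with elements `outbred` and `inbred`.
#' @export
read_assay_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("population", "generation", "scheme", "F_parents",
              "F_offspring", "pair_id", "pupae_count")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("assay table is missing columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(tab$scheme %in% c("outbred", "inbred")),
            all(tab$pupae_count >= 0))
  tab
}

#' @rdname read_assay_table
#' @export
write_assay_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_assay_table
#' @export
assays_from_table <- function(table) {
  stopifnot(length(unique(table$population)) == 1,
            length(unique(table$generation)) == 1)
  mk <- function(sch) {
    rows <- table[table$scheme == sch, , drop = FALSE]
    if (nrow(rows) == 0) stop("no ", sch, " rows in this stratum")
    productivity_assay(rows$pupae_count, sch,
                       f_parents = rows$F_parents[1],
                       f_offspring = rows$F_offspring[1])
  }
  list(outbred = mk("outbred"), inbred = mk("inbred"))
}
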