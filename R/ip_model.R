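#' Parameter set for inbreeding-purging predictions
#'
#' Bundles the quantities that drive the inbreeding-purging (IP) theory for
#' one population lineage: the effective size that sets the inbreeding rate,
#' the purging coefficient `d = s(1/2 - h)` summarising how much of the
#' deleterious homozygous effect is concealed in heterozygotes, the initial
#' inbreeding load in lethal equivalents, and (optionally) the initial
#' expected productivity.
#'
#' @param ne Effective population size (> 0).
#' @param d Purging coefficient, in `[0, 0.5]`. `d = 0` recovers the neutral
#'   (pure drift) model.
#' @param delta0 Initial inbreeding load (lethal equivalents). Any real value
#'   is accepted; negative point estimates arise from sampling error.
#' @param p0 Initial expected mean productivity (pupae per pair, > 0).
#'   Optional; only needed for fitness predictions on the observed scale.
#' @return An object of class `ip_params`.
#' @examples
#' ip_params(ne = 1376, d = 0.3, delta0 = 2.0)
#' @export
ip_params <- function(ne, d = 0, delta0 = 0, p0 = NA_real_) {
  stopifnot(is.numeric(ne), length(ne) == 1L, is.finite(ne), ne > 0)
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, d <= 0.5)
  stopifnot(is.numeric(delta0), length(delta0) == 1L, is.finite(delta0))
  if (!is.na(p0)) stopifnot(is.numeric(p0), p0 > 0)
  structure(list(ne = ne, d = d, delta0 = delta0, p0 = p0),
            class = "ip_params")
}

#' @export
print.ip_params <- function(x, ...) {
  cat(sprintf("IP parameters: Ne = %g, d = %g, delta0 = %g, P0 = %g\n",
              x$ne, x$d, x$delta0, x$p0))
  invisible(x)
}

#' Wright's inbreeding coefficient under constant effective size
#'
#' `F_t = 1 - (1 - 1/(2 Ne))^t`: the expected identity by descent after `t`
#' generations of random mating at constant effective size `Ne`.
#'
#' @param ne Effective population size (> 0).
#' @param t Generation index (non-negative integer); may be a vector.
#' @return Inbreeding coefficient(s) in `[0, 1)`.
#' @examples
#' wright_inbreeding(43, 153)
#' @export
wright_inbreeding <- function(ne, t) {
  stopifnot(is.numeric(ne), length(ne) == 1L, ne > 0)
  stopifnot(is.numeric(t), all(t >= 0), all(t == round(t)))
  1 - (1 - 1 / (2 * ne))^t
}

#' Purged inbreeding coefficient trajectory
#'
#' Iterates the purged-inbreeding recursion
#' `g_t = [1/(2Ne) + (1 - 1/(2Ne)) g_{t-1}] (1 - 2 d F_{t-1})`
#' from `g_0 = 0`, alongside Wright's `F_t`. `g` discounts the part of the
#' identity by descent whose deleterious effect purging has already removed;
#' for `d = 0` it collapses to `F` exactly.
#'
#' @param params An [ip_params()] object (only `ne` and `d` are used).
#' @param t_max Prediction horizon (number of generations, >= 0).
#' @return A data frame with columns `t`, `F`, `g` for generations
#'   `0..t_max`, carrying the generating parameters in attribute `"params"`.
#' @examples
#' tr <- ip_trajectory(ip_params(ne = 43, d = 0.3), 153)
#' tail(tr)
#' @export
ip_trajectory <- function(params, t_max) {
  stopifnot(inherits(params, "ip_params"))
  stopifnot(is.numeric(t_max), length(t_max) == 1L, t_max >= 0,
            t_max == round(t_max))
  a <- 1 / (2 * params$ne)
  t <- 0:t_max
  f <- wright_inbreeding(params$ne, t)
  g <- numeric(t_max + 1)
  for (i in seq_len(t_max)) {
    # F_{t-1} damps the increment; at i = 1 the factor is 1 so g_1 = 1/(2Ne)
    g[i + 1] <- (a + (1 - a) * g[i]) * (1 - 2 * params$d * f[i])
  }
  out <- data.frame(t = t, F = f, g = g)
  attr(out, "params") <- params
  out
}

#' Asymptotic purged inbreeding coefficient
#'
#' Fixed point of the purged-inbreeding recursion once `F` has reached 1:
#' `g_inf = a (1 - 2d) / (1 - (1 - a)(1 - 2d))` with `a = 1/(2 Ne)`. This is
#' the fraction of identity by descent that escapes purging in the long run.
#'
#' @inheritParams ip_trajectory
#' @return The asymptote of `g_t` as `t` grows.
#' @export
purged_inbreeding_asymptote <- function(params) {
  stopifnot(inherits(params, "ip_params"))
  a <- 1 / (2 * params$ne)
  a * (1 - 2 * params$d) / (1 - (1 - a) * (1 - 2 * params$d))
}

.check_traj <- function(params, traj) {
  p <- attr(traj, "params")
  if (is.null(p) || !isTRUE(all.equal(p$ne, params$ne)) ||
      !isTRUE(all.equal(p$d, params$d))) {
    stop("trajectory was not generated with the same Ne and d as `params`")
  }
  invisible(TRUE)
}

#' Predicted mean fitness trajectory
#'
#' Expected mean productivity under inbreeding depression: the neutral
#' (drift-only) model `E[P_t] = P0 exp(-delta0 F_t)` or the
#' inbreeding-purging model `E[P_t] = P0 exp(-delta0 g_t)`.
#'
#' @param params An [ip_params()] object; `p0` may be `NA`, in which case the
#'   founder mean is taken as 1 (relative fitness scale).
#' @param traj Trajectory from [ip_trajectory()] built with the same
#'   parameters; if `NULL`, one is built for `t_max`.
#' @param model `"purging"` (uses `g_t`) or `"neutral"` (uses `F_t`).
#' @param t_max Horizon used when `traj` is `NULL`.
#' @return Numeric vector of expected productivities for generations
#'   `0..t_max`.
#' @examples
#' p <- ip_params(ne = 43, d = 0.3, delta0 = 1.402, p0 = 1)
#' predict_mean_fitness(p, model = "purging", t_max = 153)[154]
#' @export
predict_mean_fitness <- function(params, traj = NULL,
                                 model = c("purging", "neutral"),
                                 t_max = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "ip_params"))
  if (is.null(traj)) {
    stopifnot(!is.null(t_max))
    traj <- ip_trajectory(params, t_max)
  } else {
    .check_traj(params, traj)
  }
  p0 <- if (is.na(params$p0)) 1 else params$p0
  expo <- if (model == "purging") traj$g else traj$F
  p0 * exp(-params$delta0 * expo)
}

#' Predicted inbreeding-load trajectory
#'
#' Expected remaining inbreeding load: the neutral model
#' `E[delta_t] = delta0 (1 - F_t)` (load eroded by random fixation/loss
#' alone) or the inbreeding-purging model
#' `E[delta_t] = delta0 g_t (1 - F_t) / F_t`, which additionally discounts
#' the load removed by purging. At `t = 0` the purging expression is defined
#' by its limit `g_t/F_t -> 1`, i.e. `delta0`.
#'
#' @inheritParams predict_mean_fitness
#' @return Numeric vector of expected loads for generations `0..t_max`.
#' @examples
#' p <- ip_params(ne = 1000, delta0 = 1.85)
#' predict_inbreeding_load(p, model = "neutral", t_max = 125)[126]
#' @export
predict_inbreeding_load <- function(params, traj = NULL,
                                    model = c("purging", "neutral"),
                                    t_max = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "ip_params"))
  if (is.null(traj)) {
    stopifnot(!is.null(t_max))
    traj <- ip_trajectory(params, t_max)
  } else {
    .check_traj(params, traj)
  }
  if (model == "neutral") {
    params$delta0 * (1 - traj$F)
  } else {
    ratio <- ifelse(traj$t == 0, 1, traj$g / traj$F)
    params$delta0 * ratio * (1 - traj$F)
  }
}

#' Predicted productivity of a derived line relative to its base population
#'
#' Ratio `E[P_line(t_line)] / E[P_base(t_base)]` of the expected mean
#' productivities of a derived line and of the base population it was split
#' from, each predicted from its own `Ne`, `d` and initial load with a
#' common founder mean (which cancels). Generations are the synchronous
#' calendar pair: line generation `t_line` is assayed at the same time as
#' base generation `t_base`.
#'
#' @param base,line [ip_params()] objects for the base population and the
#'   derived line.
#' @param t_line,t_base Generation of the line and of the base population.
#' @param model `"purging"` or `"neutral"`.
#' @return The predicted productivity ratio.
#' @examples
#' predict_relative_fitness(ip_params(1376, 0, 2.0), ip_params(43, 0, 1.402),
#'                          t_line = 153, t_base = 234, model = "neutral")
#' @export
predict_relative_fitness <- function(base, line, t_line, t_base,
                                     model = c("purging", "neutral")) {
  model <- match.arg(model)
  stopifnot(inherits(base, "ip_params"), inherits(line, "ip_params"))
  bb <- ip_params(base$ne, base$d, base$delta0, 1)
  ll <- ip_params(line$ne, line$d, line$delta0, 1)
  p_line <- predict_mean_fitness(ll, model = model, t_max = t_line)[t_line + 1]
  p_base <- predict_mean_fitness(bb, model = model, t_max = t_base)[t_base + 1]
  p_line / p_base
}

#' Least-squares estimate of the purging coefficient
#'
#' Estimates the effective purging coefficient `d` from an observed
#' inbreeding-load time series by minimising
#' `sum_t (delta_hat_t - E[delta_t | d])^2`, where the expectation is the
#' purging-model load prediction at fixed `Ne` and `delta0`. The sum of
#' squares is scanned on a dense grid over `[0, 0.5]` (step `grid_step`,
#' ties broken toward smaller `d`) and the best grid cell is refined with
#' one-dimensional optimisation. An optional residual bootstrap gives a
#' confidence interval.
#'
#' @param t Generations at which the load was observed (>= 2 values).
#' @param delta_obs Observed load estimates, same length as `t`.
#' @param ne Effective size of the observed population.
#' @param delta0 Initial load used by the prediction.
#' @param grid_step Grid resolution for the initial scan.
#' @param bootstrap Number of residual-bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A list with `d` (the estimate), `sse`, and when bootstrapped,
#'   `d_boot` (replicate estimates) and `ci` (percentile 95% interval).
#' @examples
#' p <- ip_params(ne = 1376, d = 0.3, delta0 = 2)
#' tt <- c(0, 30, 60, 90, 120)
#' dd <- predict_inbreeding_load(p, model = "purging", t_max = 120)[tt + 1]
#' fit_purging_coefficient(tt, dd, ne = 1376, delta0 = 2)$d
#' @export
fit_purging_coefficient <- function(t, delta_obs, ne, delta0,
                                    grid_step = 0.001, bootstrap = 0,
                                    seed = NULL) {
  stopifnot(length(t) == length(delta_obs), length(t) >= 1)
  if (length(t) == 0) stop("empty observed series")
  stopifnot(all(t >= 0), all(t == round(t)))
  t_max <- max(t)

  pred <- function(d) {
    p <- ip_params(ne, d, delta0)
    predict_inbreeding_load(p, model = "purging", t_max = t_max)[t + 1]
  }
  sse <- function(d, obs) sum((obs - pred(d))^2)

  point_fit <- function(obs) {
    grid <- seq(0, 0.5, by = grid_step)
    vals <- vapply(grid, sse, numeric(1), obs = obs)
    i <- which.min(vals)  # which.min takes the first minimum: smaller d wins ties
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    if (lo < hi) {
      op <- stats::optimize(sse, c(lo, hi), obs = obs, tol = 1e-8)
      if (op$objective < vals[i] - 1e-15) return(op$minimum)
    }
    grid[i]
  }

  d_hat <- point_fit(delta_obs)
  out <- list(d = d_hat, sse = sse(d_hat, delta_obs))
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    fitted <- pred(d_hat)
    res <- delta_obs - fitted
    out$d_boot <- vapply(seq_len(bootstrap), function(b) {
      point_fit(fitted + sample(res, length(res), replace = TRUE))
    }, numeric(1))
    out$ci <- unname(stats::quantile(out$d_boot, c(0.025, 0.975)))
  }
  out
}
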