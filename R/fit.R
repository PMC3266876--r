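# Bounded smooth reparameterization: theta in R maps to
# exp(log(lo) + (log(hi) - log(lo)) * plogis(theta)).
to_bounded <- function(theta, lo, hi)
  exp(log(lo) + (log(hi) - log(lo)) * stats::plogis(theta))
from_bounded <- function(x, lo, hi) {
  f <- (log(x) - log(lo)) / (log(hi) - log(lo))
  stats::qlogis(pmin(pmax(f, 1e-8), 1 - 1e-8))
}

#' Maximum-likelihood fit of the kinetic parameters at one temperature
#'
#' Multi-start bounded Nelder-Mead optimization of
#' [negloglik_timecourse()] over the mean oogenesis capacity
#' `mu_kmax`, the sperm death rate `k_d` and (at stressful
#' temperatures) the non-robust fraction `delta`. Rates are optimized
#' on a log scale through a smooth bounded transform; `delta` is fixed
#' at `delta_fixed` when `fit_delta = FALSE` (it is indistinguishable
#' from zero at permissive temperatures, 25 degrees C and below).
#'
#' @param table an egg-count table from a single temperature
#'   (>= 3 time points, >= 10 individuals).
#' @param temp_C the table's temperature (degrees C).
#' @param pp a [population_params()] object with the known
#'   heterogeneity hyper-parameters (e.g. sperm cache statistics
#'   inferred from permissive-temperature broods via
#'   [infer_sperm_from_brood()]).
#' @param k_hat sperm half-saturation constant (held fixed).
#' @param fit_delta estimate `delta` (default: only at 28 degrees C
#'   and above).
#' @param delta_fixed value of `delta` when not estimated.
#' @param bounds named list of `c(lo, hi)` box bounds for `mu_kmax`,
#'   `k_d`, `delta`.
#' @param n_starts number of optimization starts (1 deterministic +
#'   `n_starts - 1` random).
#' @param seed integer seed for the random starts.
#' @param n_nodes_z,n_nodes_k,var_floor passed to
#'   [negloglik_timecourse()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `worm_fit`: `estimates` (list with
#'   `mu_kmax`, `k_d`, `delta`), `loglik`, `temp_C`, `k_hat`,
#'   `convergence` (per-start optim codes), `n_starts`, `seed`, `pp`.
#' @export
fit_mle <- function(table, temp_C, pp, k_hat = 100,
                    fit_delta = temp_C >= 28, delta_fixed = 0,
                    bounds = list(mu_kmax = c(0.5, 100),
                                  k_d = c(1e-6, 10),
                                  delta = c(1e-4, 0.999)),
                    n_starts = 8, seed = NULL, n_nodes_z = 5,
                    n_nodes_k = 5, var_floor = 1 / 3, maxit = 400) {
  validate_egg_table(table)
  if (length(unique(table$time_h)) < 3 ||
      length(unique(table$individual_id)) < 10)
    stop("table too small to fit: need >= 3 time points and >= 10 individuals")
  if (length(unique(table$temp_C)) != 1)
    stop("table must come from a single temperature")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nm <- if (fit_delta) c("mu_kmax", "k_d", "delta") else c("mu_kmax", "k_d")
  lo <- vapply(bounds[nm], `[`, numeric(1), 1)
  hi <- vapply(bounds[nm], `[`, numeric(1), 2)
  obj <- function(theta) {
    x <- to_bounded(theta, lo, hi)
    negloglik_timecourse(table, mu_kmax = x[1], k_d = x[2],
                         delta = if (fit_delta) x[3] else delta_fixed,
                         pp = pp, k_hat = k_hat, n_nodes_z = n_nodes_z,
                         n_nodes_k = n_nodes_k, var_floor = var_floor)
  }
  start0 <- from_bounded(
    c(mu_kmax = 5, k_d = 0.05, delta = 0.3)[nm], lo, hi)
  starts <- list(start0)
  for (i in seq_len(max(n_starts - 1, 0)))
    starts[[i + 1]] <- stats::runif(length(nm), -2, 2)
  best <- NULL
  conv <- integer(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  x <- to_bounded(best$par, lo, hi)
  est <- list(mu_kmax = unname(x[1]), k_d = unname(x[2]),
              delta = if (fit_delta) unname(x[3]) else delta_fixed)
  structure(list(estimates = est, loglik = -best$value, temp_C = temp_C,
                 k_hat = k_hat, convergence = conv, n_starts = length(starts),
                 seed = seed, pp = pp, fit_delta = fit_delta,
                 bounds = bounds[nm]),
            class = "worm_fit")
}

#' @export
print.worm_fit <- function(x, ...) {
  cat(sprintf("MLE fit at %g C: mu_kmax = %.4g eggs/h, k_d = %.4g /h, delta = %.4g\n",
              x$temp_C, x$estimates$mu_kmax, x$estimates$k_d,
              x$estimates$delta))
  cat(sprintf("  loglik = %.3f (%d starts; optim codes: %s)\n", x$loglik,
              x$n_starts, paste(x$convergence, collapse = " ")))
  invisible(x)
}

#' Fit exponential temperature laws through per-temperature estimates
#'
#' Least-squares line through `(T, log parameter)` for each of
#' `k_max`, `k_d` and `delta`. Non-positive (or missing) estimates
#' cannot enter a log-linear fit and are excluded with a warning, as
#' are estimates pinned to an optimization bound (a parameter driven
#' to its box edge carries no information about its value — e.g. the
#' sperm death rate at 20 degrees C, whose effect on a full brood is
#' below one egg). Fits where `delta` was fixed at zero contribute no
#' `delta` point, so the `delta` law is anchored on the stressful
#' temperatures. At least two positive points per kinetic law are
#' required; if fewer than two `delta` points remain the `delta` law
#' degrades to identically zero with a warning.
#'
#' @param fits list of `worm_fit` objects (>= 2 distinct
#'   temperatures) for the kinetic laws; the study design trains them
#'   on 20/25/29 degrees C.
#' @param delta_fits list of `worm_fit` objects used for the `delta`
#'   law (default: the same fits); the design anchors it on the
#'   temperatures where `delta` is nonzero (28/29 degrees C).
#' @param delta_cap,range passed to [temperature_law()].
#' @return A [temperature_law()] object (with `k_hat` taken from the
#'   fits, which must agree).
#' @export
fit_temperature_law <- function(fits, delta_fits = fits, delta_cap = 1,
                                range = c(20, 30)) {
  if (!all(vapply(c(fits, delta_fits), inherits, logical(1), "worm_fit")))
    stop("`fits` must be a list of worm_fit objects")
  k_hats <- unique(vapply(c(fits, delta_fits), `[[`, numeric(1), "k_hat"))
  if (length(k_hats) != 1) stop("fits disagree on k_hat")
  get_law <- function(fits, field, label, required = TRUE) {
    temps <- vapply(fits, `[[`, numeric(1), "temp_C")
    v <- vapply(fits, function(f) f$estimates[[field]], numeric(1))
    at_bound <- vapply(fits, function(f) {
      b <- f$bounds[[field]]
      est <- f$estimates[[field]]
      !is.null(b) && is.finite(est) && est > 0 &&
        (est / b[1] < 1.05 || est / b[2] > 1 / 1.05)
    }, logical(1))
    keep <- is.finite(v) & v > 0 & !at_bound
    if (any(!keep))
      warning(sprintf("%d %s estimate(s) excluded from the %s log-linear fit (non-positive or at an optimization bound)",
                      sum(!keep), label, label))
    if (sum(keep) < 2) {
      if (required)
        stop(sprintf("need >= 2 positive %s estimates at distinct temperatures", label))
      warning(sprintf("fewer than 2 positive %s estimates: %s law set to zero",
                      label, label))
      return(c(a = -1e6, b = 0))
    }
    cf <- stats::coef(stats::lm(log(v[keep]) ~ temps[keep]))
    c(a = unname(cf[1]), b = unname(cf[2]))
  }
  temperature_law(k_max = get_law(fits, "mu_kmax", "k_max"),
                  k_d = get_law(fits, "k_d", "k_d"),
                  delta = get_law(delta_fits, "delta", "delta",
                                  required = FALSE),
                  k_hat = k_hats, delta_cap = delta_cap, range = range)
}

#' Predict cohort egg-laying dynamics at a temperature
#'
#' Monte-Carlo prediction: draws a synthetic cohort at the law-implied
#' parameters (the only condition-specific input is the temperature)
#' and summarizes the per-animal cumulative egg curves at the protocol
#' observation times.
#'
#' @param law a [temperature_law()] object.
#' @param pp a [population_params()] object (its `delta` is replaced
#'   by the law's value at `temp_C`).
#' @param temp_C prediction temperature (degrees C).
#' @param proto an [observation_protocol()]; predictions are reported
#'   at the union of its dense and sparse times.
#' @param n_rep number of simulated animals.
#' @param seed integer seed.
#' @return A data frame with columns `time_h`, `mean`, `sd`, `median`,
#'   `lo`, `hi` (mean +/- 1 s.d. envelopes), with the simulated
#'   per-animal terminal broods attached as attribute `broods` and the
#'   law-implied parameters as attribute `params`.
#' @export
predict_cohort <- function(law, pp, temp_C, proto = observation_protocol(),
                           n_rep = 200, seed = NULL) {
  at <- params_at_temperature(temp_C, law)
  pp$delta <- at$delta
  pp$mu_kmax <- at$params$k_max
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  inds <- draw_individual(pp, n_rep)
  times <- sort(unique(c(proto$dense_times, proto$sparse_times)))
  E <- qss_egg_curves(inds$S0, inds$k_max_i, at$params$k_hat, at$params$k_d,
                      inds$t0, times)
  counts <- round(E)
  kd <- at$params$k_d
  broods <- if (kd == 0) inds$S0
  else (inds$k_max_i / kd) *
    log1p(kd * inds$S0 / (inds$k_max_i + kd * at$params$k_hat))
  out <- data.frame(time_h = times,
                    mean = colMeans(counts),
                    sd = apply(counts, 2, stats::sd),
                    median = apply(counts, 2, stats::median))
  out$lo <- out$mean - out$sd
  out$hi <- out$mean + out$sd
  structure(out, broods = round(broods), params = at$params,
            delta = at$delta, n_rep = n_rep, seed = seed)
}

#' Infer sperm-cache hyper-parameters from permissive-temperature broods
#'
#' At 20 degrees C sperm death is negligible, so each animal's total
#' brood equals its sperm cache and the brood distribution directly
#' estimates the sperm-cache distribution. Supply either the raw
#' per-animal broods or a printed `mean +/- sd` summary.
#'
#' @param broods numeric vector of per-animal total broods (n >= 2).
#' @param mean,sd alternatively, a published summary.
#' @return List with `mu_S` and `sigma_S` (sperm).
#' @examples
#' infer_sperm_from_brood(mean = 437, sd = 40)  # tra-3 at 20 C
#' @export
infer_sperm_from_brood <- function(broods = NULL, mean = NULL, sd = NULL) {
  if (!is.null(broods)) {
    if (length(broods) < 2) stop("need >= 2 broods")
    if (any(!is.finite(broods) | broods < 0))
      stop("broods must be finite and >= 0")
    return(list(mu_S = base::mean(broods), sigma_S = stats::sd(broods)))
  }
  if (is.null(mean) || is.null(sd)) stop("supply `broods` or both `mean` and `sd`")
  if (mean < 0 || sd < 0) stop("mean and sd must be >= 0")
  list(mu_S = mean, sigma_S = sd)
}
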