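new_trajectory <- function(df, params, model_form) {
  structure(df, class = c("worm_trajectory", "data.frame"),
            params = params, model_form = model_form)
}

#' Integrate the full gamete-flow model
#'
#' Integrates the mass-action system for one animal from the onset of
#' oogenesis: `dO/dt = k_g - k_s O - k_do O - k_o O S_a`,
#' `dS_a/dt = -k_o O S_a - k_d S_a`, `dE/dt = k_o O S_a`,
#' `dS_d/dt = k_d S_a`, `dO_d/dt = k_do O`, starting from
#' `O = E = S_d = O_d = 0`, `S_a = S0`. Every laid egg consumes one
#' sperm, so `E + S_a + S_d = S0` is conserved up to solver tolerance.
#'
#' @param p a [kinetic_params()] object.
#' @param S0 initial sperm cache (>= 0).
#' @param horizon integration horizon in hours (ignored when `grid`
#'   given).
#' @param grid output time grid in hours (strictly increasing, from 0);
#'   default 201 equispaced points on `[0, horizon]`.
#' @param rtol,atol solver tolerances (lsoda).
#' @return A `worm_trajectory` data frame with columns `time_h`, `O`,
#'   `S_a`, `E`, `S_d` (and `O_d` when `k_do > 0`).
#' @seealso [integrate_qss()] for the reduced model.
#' @export
integrate_full <- function(p, S0, horizon = 120, grid = NULL,
                           rtol = 1e-8, atol = 1e-8) {
  stopifnot_params(p)
  if (!is.numeric(S0) || length(S0) != 1 || !is.finite(S0) || S0 < 0)
    stop("S0 must be a single finite number >= 0")
  if (is.null(grid)) grid <- seq(0, horizon, length.out = 201)
  check_grid(grid)
  rhs <- function(t, y, pars) {
    O <- max(y[1], 0); S <- max(y[2], 0)
    ov <- p$k_o * O * S
    list(c(p$k_g - p$k_s * O - p$k_do * O - ov,
           -ov - p$k_d * S,
           ov,
           p$k_d * S,
           p$k_do * O))
  }
  out <- deSolve::lsoda(c(O = 0, S_a = S0, E = 0, S_d = 0, O_d = 0),
                        grid, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("full-model integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  df <- data.frame(time_h = out[, "time"], O = pmax(out[, "O"], 0),
                   S_a = pmax(out[, "S_a"], 0), E = out[, "E"],
                   S_d = out[, "S_d"])
  if (p$k_do > 0) df$O_d <- out[, "O_d"]
  new_trajectory(df, p, "full")
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2 || any(!is.finite(grid)) ||
      any(diff(grid) <= 0) || grid[1] != 0)
    stop("`grid` must be strictly increasing and start at 0")
  invisible(grid)
}

#' Integrate the quasi-steady-state model
#'
#' Integrates the reduced system `dE/dt = k_max S_a / (k_hat + S_a)`,
#' `dS_a/dt = -dE/dt - k_d S_a` (plus the dead-sperm sink
#' `dS_d/dt = k_d S_a`). With `to_cessation = TRUE` the horizon is
#' extended (doubled) until the egg-laying rate falls below
#' `rate_tol`, i.e. until egg-laying has numerically ceased.
#'
#' @inheritParams integrate_full
#' @param to_cessation integrate until the egg-laying rate drops below
#'   `rate_tol` instead of to a fixed horizon.
#' @param rate_tol cessation threshold on the egg-laying rate (eggs/h).
#' @return A `worm_trajectory` data frame with columns `time_h`, `O`
#'   (the quasi-steady-state oocyte pool), `S_a`, `E`, `S_d`.
#' @examples
#' p <- kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0)
#' tr <- integrate_qss(p, S0 = 300, to_cessation = TRUE)
#' round(tail(tr$E, 1)) # 300: every sperm is used when none die
#' @export
integrate_qss <- function(p, S0, horizon = 120, grid = NULL,
                          to_cessation = FALSE, rate_tol = 1e-9,
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot_params(p)
  if (!is.numeric(S0) || length(S0) != 1 || !is.finite(S0) || S0 < 0)
    stop("S0 must be a single finite number >= 0")
  run <- function(grid) {
    rhs <- function(t, y, pars) {
      S <- max(y[1], 0)
      lay <- p$k_max * S / (p$k_hat + S)
      list(c(-lay - p$k_d * S, lay, p$k_d * S))
    }
    out <- deSolve::lsoda(c(S_a = S0, E = 0, S_d = 0), grid, rhs,
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop("QSS integration failed (lsoda istate ", attr(out, "istate")[1], ")")
    out
  }
  if (to_cessation) {
    h <- max(horizon, 1)
    repeat {
      out <- run(seq(0, h, length.out = 401))
      if (qss_egg_rate(max(out[nrow(out), "S_a"], 0), p) < rate_tol || S0 == 0)
        break
      h <- 2 * h
      if (h > 1e6) stop("no cessation reached before 1e6 h; check parameters")
    }
  } else {
    if (is.null(grid)) grid <- seq(0, horizon, length.out = 201)
    check_grid(grid)
    out <- run(grid)
  }
  S <- pmax(out[, "S_a"], 0)
  df <- data.frame(time_h = out[, "time"],
                   O = if (p$k_s + p$k_o * max(S) > 0)
                     qss_oocyte_count(S, p) else NA_real_,
                   S_a = S, E = out[, "E"], S_d = out[, "S_d"])
  new_trajectory(df, p, "qss")
}

#' Closed-form mean-field solution of the quasi-steady-state model
#'
#' The sperm equation `dS/dt = -k_max S/(k_hat + S) - k_d S` is
#' separable. With `A = k_max + k_d k_hat` its implicit solution is
#' `(k_hat/A) log(S0/S) + (k_max/(A k_d)) log((A + k_d S0)/(A + k_d S)) = t`
#' (for `k_d = 0`: `k_hat log(S0/S) + (S0 - S) = k_max t`), which is
#' solved for `S(t)` by bracketed root finding; the egg count follows
#' analytically as `E = (k_max/k_d) log((A + k_d S0)/(A + k_d S))`
#' (`E = S0 - S` when `k_d = 0`). This closed form is the independent
#' oracle for [integrate_qss()].
#'
#' @param p a [kinetic_params()] object (QSS form; `k_max, k_hat > 0`).
#' @param S0 initial sperm cache.
#' @param t vector of times (hours, >= 0).
#' @return A data frame with columns `time_h`, `S_a`, `E`.
#' @export
mean_field_solution <- function(p, S0, t) {
  stopifnot_params(p)
  if (p$k_max <= 0 || !is.finite(p$k_hat) || p$k_hat <= 0)
    stop("mean-field solution requires k_max > 0 and finite k_hat > 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (S0 == 0)
    return(data.frame(time_h = t, S_a = 0, E = 0))
  A <- p$k_max + p$k_d * p$k_hat
  elapsed <- function(S) {                      # time to deplete S0 -> S
    if (p$k_d > 0)
      (p$k_hat / A) * log(S0 / S) +
        (p$k_max / (A * p$k_d)) * log((A + p$k_d * S0) / (A + p$k_d * S))
    else
      (p$k_hat * log(S0 / S) + (S0 - S)) / p$k_max
  }
  S_of_t <- vapply(t, function(ti) {
    if (ti == 0) return(S0)
    lo <- S0 * 1e-300
    if (elapsed(lo) < ti) return(0)             # numerically fully depleted
    uniroot(function(S) elapsed(S) - ti, lower = lo, upper = S0,
            tol = 1e-13 * S0)$root
  }, numeric(1))
  E <- if (p$k_d > 0)
    (p$k_max / p$k_d) * log((A + p$k_d * S0) / (A + p$k_d * S_of_t))
  else S0 - S_of_t
  data.frame(time_h = t, S_a = S_of_t, E = E)
}

#' Total brood at egg-laying cessation
#'
#' Closed-form terminal egg count of the quasi-steady-state model:
#' `S0` when `k_d = 0` (every sperm is eventually used), otherwise
#' `(k_max/k_d) * log(1 + k_d S0 / (k_max + k_d k_hat)) < S0`.
#'
#' @inheritParams mean_field_solution
#' @return Expected total brood (eggs).
#' @export
brood_total <- function(p, S0) {
  stopifnot_params(p)
  if (any(S0 < 0)) stop("S0 must be >= 0")
  if (p$k_d == 0) return(S0 + 0)
  (p$k_max / p$k_d) * log1p(p$k_d * S0 / (p$k_max + p$k_d * p$k_hat))
}

# Stacked QSS egg curves for many individuals in one solver call.
# S0, kmax, t0: vectors (one entry per individual); khat, kd scalars.
# Returns an n_individuals x length(times) matrix of E evaluated at the
# per-individual shifted times max(0, times - t0[i]).
qss_egg_curves <- function(S0, kmax, khat, kd, t0, times,
                           rtol = 1e-8, atol = 1e-8) {
  n <- length(S0)
  stopifnot(length(kmax) == n, length(t0) == n)
  shifted <- outer(times, t0, "-")              # n_times x n
  shifted[shifted < 0] <- 0
  grid <- sort(unique(c(0, as.vector(shifted))))
  E <- matrix(0, n, length(times))
  if (length(grid) < 2 || all(S0 == 0)) return(E)
  rhs <- function(t, y, pars) {
    S <- pmax(y[seq_len(n)], 0)
    lay <- kmax * S / (khat + S)
    list(c(-lay - kd * S, lay))
  }
  out <- deSolve::lsoda(c(S0, numeric(n)), grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("stacked QSS integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  Emat <- out[, n + 1 + seq_len(n), drop = FALSE]
  idx <- match(shifted, grid)
  dim(idx) <- dim(shifted)
  for (i in seq_len(n)) E[i, ] <- Emat[idx[, i], i]
  pmax(E, 0)
}
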