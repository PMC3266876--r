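#' Population hyper-parameters of the individual-based simulator
#'
#' Describes the between-animal heterogeneity of a cohort. A single
#' latent standard-normal draw `z` per animal sets both its sperm
#' cache `S0 = round(mu_S + sigma_S z)` and its onset delay
#' `t0 = max(0, mu_t0 + sigma_t0 z)` (high sperm count is coupled to a
#' delayed onset of oogenesis: both are determined by how long the
#' germline keeps making sperm before the switch to oogenesis).
#' Independently, each animal is non-robust with probability `delta`;
#' its oogenesis capacity is drawn as
#' `k_max_i ~ N(mu_kmax * (1 or kmax_ratio_nonrobust), sigma_kmax)`,
#' truncated at zero.
#'
#' @param mu_S,sigma_S mean and s.d. of the sperm cache (sperm).
#' @param mu_t0,sigma_t0 mean and s.d. of the onset delay (h).
#' @param mu_kmax,sigma_kmax mean and s.d. of the robust-class
#'   oogenesis capacity (eggs/h).
#' @param kmax_ratio_nonrobust multiplicative factor (< 1) applied to
#'   `mu_kmax` for the non-robust class.
#' @param delta probability that an animal is non-robust.
#' @return An object of class `population_params`.
#' @export
population_params <- function(mu_S = 300, sigma_S = 45, mu_t0 = 4,
                              sigma_t0 = 1.5, mu_kmax = 7.5,
                              sigma_kmax = 0.75,
                              kmax_ratio_nonrobust = 0.25, delta = 0) {
  if (any(c(sigma_S, sigma_t0, sigma_kmax) < 0)) stop("sigmas must be >= 0")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (kmax_ratio_nonrobust <= 0 || kmax_ratio_nonrobust > 1)
    stop("kmax_ratio_nonrobust must be in (0, 1]")
  if (mu_S < 0 || mu_kmax <= 0) stop("mu_S must be >= 0 and mu_kmax > 0")
  structure(list(mu_S = mu_S, sigma_S = sigma_S, mu_t0 = mu_t0,
                 sigma_t0 = sigma_t0, mu_kmax = mu_kmax,
                 sigma_kmax = sigma_kmax,
                 kmax_ratio_nonrobust = kmax_ratio_nonrobust,
                 delta = delta),
            class = "population_params")
}

#' Observation protocol of an egg-counting experiment
#'
#' Mirrors the study design: for the first `dense_horizon` hours eggs
#' are scored every `dense_interval` hours on fresh animals at each
#' time point (destructive, cross-sectional sampling, to avoid
#' temperature fluctuations from repeated handling); separately,
#' `n_longitudinal` animals are transferred and counted every
#' `sparse_interval` hours until `sparse_horizon` (longitudinal
#' sampling, chosen long enough for egg-laying to cease).
#'
#' @param dense_interval,dense_horizon cross-sectional schedule (h).
#' @param sparse_interval,sparse_horizon longitudinal schedule (h).
#' @param n_per_dense animals destructively scored per dense time point.
#' @param n_longitudinal animals followed longitudinally.
#' @return An object of class `observation_protocol` with the derived
#'   `dense_times` and `sparse_times` grids.
#' @export
observation_protocol <- function(dense_interval = 2, dense_horizon = 12,
                                 sparse_interval = 12, sparse_horizon = 240,
                                 n_per_dense = 8, n_longitudinal = 30) {
  if (dense_interval <= 0 || sparse_interval <= 0) stop("intervals must be > 0")
  if (n_per_dense < 0 || n_longitudinal < 0) stop("counts must be >= 0")
  structure(list(dense_interval = dense_interval, dense_horizon = dense_horizon,
                 sparse_interval = sparse_interval,
                 sparse_horizon = sparse_horizon,
                 n_per_dense = n_per_dense, n_longitudinal = n_longitudinal,
                 dense_times = seq(dense_interval, dense_horizon,
                                   by = dense_interval),
                 sparse_times = seq(sparse_interval, sparse_horizon,
                                    by = sparse_interval)),
            class = "observation_protocol")
}

#' Draw heterogeneous individuals
#'
#' Samples `n` animals from the population model using the current RNG
#' state (seed with [set.seed()] or via the `seed` argument of
#' [simulate_cohort()]).
#'
#' @param pp a [population_params()] object.
#' @param n number of animals.
#' @return A data frame with one row per animal: `id`, `z` (shared
#'   latent draw), `S0`, `t0`, `k_max_i`, `robust`.
#' @export
draw_individual <- function(pp, n = 1) {
  if (!inherits(pp, "population_params")) stop("`pp` must be population_params")
  z <- rnorm(n)
  robust <- runif(n) >= pp$delta
  mu_k <- pp$mu_kmax * ifelse(robust, 1, pp$kmax_ratio_nonrobust)
  data.frame(id = seq_len(n), z = z,
             S0 = pmax(0, round(pp$mu_S + pp$sigma_S * z)),
             t0 = pmax(0, pp$mu_t0 + pp$sigma_t0 * z),
             k_max_i = pmax(1e-6, rnorm(n, mu_k, pp$sigma_kmax)),
             robust = robust)
}

#' Simulate one animal's cumulative egg counts
#'
#' Integrates the quasi-steady-state model with the animal's own sperm
#' cache and capacity, delayed by its onset time `t0`; the reported
#' count at time `t` is `round(E(t - t0))` (0 before onset). Counting
#' is exact in the assay, so no noise is added beyond rounding.
#'
#' @param ind a one-row data frame from [draw_individual()] (or any
#'   list with `S0`, `t0`, `k_max_i`).
#' @param p a [kinetic_params()] object supplying `k_hat` and `k_d`
#'   (its `k_max` is replaced by the individual's `k_max_i`).
#' @param times observation times (h post temperature shift).
#' @return Integer vector of cumulative egg counts at `times`.
#' @export
simulate_individual <- function(ind, p, times) {
  stopifnot_params(p)
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be >= 0")
  E <- qss_egg_curves(S0 = ind$S0, kmax = ind$k_max_i, khat = p$k_hat,
                      kd = p$k_d, t0 = ind$t0, times = times)
  as.integer(round(E[1, ]))
}

#' Simulate a full cohort under the observation protocol
#'
#' Generates a complete synthetic egg-count table at one temperature:
#' fresh animals for every dense (cross-sectional) time point, each
#' contributing a single destructive count, plus longitudinally
#' followed animals counted at every sparse time. Parameters come
#' either from an explicit [kinetic_params()] object (with the
#' non-robust fraction taken from `pp$delta`) or from a
#' [temperature_law()] evaluated at `temp_C`. The robust-class
#' capacity mean of the drawn individuals is the condition's kinetic
#' `k_max` (it overrides `pp$mu_kmax`); `pp` supplies the spreads,
#' the non-robust ratio and the sperm/onset hyper-parameters.
#'
#' @param pp a [population_params()] object.
#' @param proto an [observation_protocol()].
#' @param temp_C cohort temperature (degrees C).
#' @param law optional [temperature_law()]; when supplied, kinetic
#'   parameters and `delta` are taken from the law at `temp_C`.
#' @param params optional [kinetic_params()] used when `law` is NULL.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param strain strain label recorded in the table.
#' @return An egg-count table: a data frame with columns
#'   `individual_id`, `strain`, `temp_C`, `time_h`, `eggs_cum`,
#'   `mode` (`cross_sectional` or `longitudinal`), carrying the drawn
#'   individuals, parameters, `delta` and seed as attributes.
#' @examples
#' tab <- simulate_cohort(population_params(), observation_protocol(),
#'                        temp_C = 20, law = default_temperature_law(),
#'                        seed = 1)
#' head(tab)
#' @export
simulate_cohort <- function(pp, proto = observation_protocol(), temp_C = 20,
                            law = NULL, params = NULL, seed = NULL,
                            strain = "N2") {
  if (!inherits(pp, "population_params")) stop("`pp` must be population_params")
  if (!inherits(proto, "observation_protocol"))
    stop("`proto` must be an observation_protocol")
  if (is.null(law) && is.null(params)) stop("supply `law` or `params`")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (!is.null(law)) {
    at <- params_at_temperature(temp_C, law)
    params <- at$params
    pp$delta <- at$delta
  }
  # the capacity mean at this condition is the kinetic k_max
  pp$mu_kmax <- params$k_max
  n_dense <- proto$n_per_dense * length(proto$dense_times)
  inds <- draw_individual(pp, n_dense + proto$n_longitudinal)
  rows <- list()
  if (n_dense > 0) {
    dense_ind <- inds[seq_len(n_dense), ]
    tp <- rep(proto$dense_times, each = proto$n_per_dense)
    E <- qss_egg_curves(dense_ind$S0, dense_ind$k_max_i, params$k_hat,
                        params$k_d, dense_ind$t0, proto$dense_times)
    counts <- as.integer(round(E[cbind(seq_len(n_dense),
                                       match(tp, proto$dense_times))]))
    rows$dense <- data.frame(
      individual_id = sprintf("%s_T%g_cs_%03d", strain, temp_C, dense_ind$id),
      strain = strain, temp_C = temp_C, time_h = tp, eggs_cum = counts,
      mode = "cross_sectional")
  }
  if (proto$n_longitudinal > 0) {
    long_ind <- inds[n_dense + seq_len(proto$n_longitudinal), ]
    E <- qss_egg_curves(long_ind$S0, long_ind$k_max_i, params$k_hat,
                        params$k_d, long_ind$t0, proto$sparse_times)
    counts <- as.integer(round(E))
    rows$long <- data.frame(
      individual_id = rep(sprintf("%s_T%g_lg_%03d", strain, temp_C,
                                  long_ind$id), times = ncol(E)),
      strain = strain, temp_C = temp_C,
      time_h = rep(proto$sparse_times, each = nrow(E)),
      eggs_cum = as.vector(counts), mode = "longitudinal")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, individuals = inds, params = params, delta = pp$delta,
            seed = seed, protocol = proto)
}

#' Per-individual total broods from an egg-count table
#'
#' Extracts the final cumulative count of each longitudinal animal
#' whose egg-laying has ceased within the observation window (last two
#' counts equal). Animals without a recorded cessation are excluded
#' with a warning.
#'
#' @param table an egg-count table (see [simulate_cohort()]).
#' @return Named numeric vector of total broods (one per longitudinal
#'   animal that reached cessation).
#' @export
brood_sizes <- function(table) {
  validate_egg_table(table)
  long <- table[table$mode == "longitudinal", ]
  if (nrow(long) == 0) stop("no longitudinal records in table")
  out <- c()
  dropped <- character()
  for (id in unique(long$individual_id)) {
    rec <- long[long$individual_id == id, ]
    rec <- rec[order(rec$time_h), ]
    n <- nrow(rec)
    if (n < 2 || rec$eggs_cum[n] != rec$eggs_cum[n - 1]) {
      dropped <- c(dropped, id)
    } else {
      out[id] <- rec$eggs_cum[n]
    }
  }
  if (length(dropped) > 0)
    warning(length(dropped), " individual(s) without cessation-time records excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  out
}
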