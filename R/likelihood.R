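# Gauss-Hermite nodes/weights for E[f(X)] with X ~ N(mu, sigma):
# sum(w * f(mu + sqrt(2) * sigma * x)) with w = w_gh / sqrt(pi).
gh_nodes <- function(n) {
  if (n == 1) return(list(x = 0, w = 1))
  g <- pracma::gaussHermite(n)
  list(x = sqrt(2) * g$x, w = g$w / sqrt(pi))
}

# Model-implied egg curves at every heterogeneity quadrature node.
# Returns E (n_nodes x n_times) and node weights w; nodes run over the
# shared latent z (sperm cache + onset), the capacity draw, and the
# robust/non-robust class mixture.
egg_node_curves <- function(times, mu_kmax, k_d, delta, pp, k_hat,
                            n_nodes_z = 5, n_nodes_k = 5) {
  if (pp$sigma_S == 0 && pp$sigma_t0 == 0) n_nodes_z <- 1
  if (pp$sigma_kmax == 0) n_nodes_k <- 1
  gz <- gh_nodes(n_nodes_z)
  gk <- gh_nodes(n_nodes_k)
  S0z <- pmax(0, pp$mu_S + pp$sigma_S * gz$x)
  t0z <- pmax(0, pp$mu_t0 + pp$sigma_t0 * gz$x)
  ratio <- if (delta > 0) c(1, pp$kmax_ratio_nonrobust) else 1
  wc <- if (delta > 0) c(1 - delta, delta) else 1
  g <- expand.grid(i = seq_along(gz$x), j = seq_along(gk$x),
                   cl = seq_along(ratio))
  kmax_v <- pmax(1e-6, mu_kmax * ratio[g$cl] + pp$sigma_kmax * gk$x[g$j])
  w <- gz$w[g$i] * gk$w[g$j] * wc[g$cl]
  E <- qss_egg_curves(S0 = S0z[g$i], kmax = kmax_v, khat = k_hat, kd = k_d,
                      t0 = t0z[g$i], times = times)
  list(E = E, w = w, times = times)
}

moments_at <- function(nodes, col) {
  v <- nodes$E[, col]
  m <- sum(nodes$w * v)
  list(mean = m, var = max(sum(nodes$w * v^2) - m^2, 0))
}

#' Negative log-likelihood of an egg-count table
#'
#' Gaussian observation model whose moments derive from the
#' individual-heterogeneity distribution: at each observation time the
#' mean and variance of the cumulative egg count are computed by
#' Gauss-Hermite quadrature over the shared latent draw (sperm cache
#' and onset delay) and the capacity draw, mixed over the robust and
#' non-robust classes with weight `delta`. Cross-sectional records are
#' independent draws of the count at their time point; longitudinal
#' records contribute their first count plus the increments between
#' consecutive counts, treated as independent between intervals. A
#' variance floor absorbs count rounding and keeps the likelihood
#' finite when all heterogeneity scales are zero.
#'
#' @param table an egg-count table from a single temperature.
#' @param mu_kmax candidate mean oogenesis capacity (eggs/h).
#' @param k_d candidate sperm death rate (1/h).
#' @param delta candidate non-robust fraction.
#' @param pp a [population_params()] object supplying the known
#'   heterogeneity hyper-parameters (sperm cache, onset, capacity
#'   spread, non-robust capacity ratio).
#' @param k_hat sperm half-saturation constant (held fixed).
#' @param n_nodes_z,n_nodes_k quadrature nodes for the latent and
#'   capacity dimensions.
#' @param var_floor additive variance floor (eggs^2).
#' @return The negative log-likelihood (a large penalty value, 1e10,
#'   if it is non-finite for the candidate).
#' @export
negloglik_timecourse <- function(table, mu_kmax, k_d, delta = 0, pp,
                                 k_hat = 100, n_nodes_z = 5, n_nodes_k = 5,
                                 var_floor = 1 / 3) {
  validate_egg_table(table)
  if (length(unique(table$temp_C)) != 1)
    stop("table must come from a single temperature")
  if (mu_kmax <= 0 || k_d < 0 || delta < 0 || delta > 1)
    return(1e10)
  times <- sort(unique(table$time_h))
  nodes <- tryCatch(
    egg_node_curves(times, mu_kmax, k_d, delta, pp, k_hat,
                    n_nodes_z, n_nodes_k),
    error = function(e) NULL)
  if (is.null(nodes)) return(1e10)
  ll <- 0
  cs <- table[table$mode == "cross_sectional", ]
  if (nrow(cs) > 0) {
    ti <- match(cs$time_h, times)
    for (u in unique(ti)) {
      mo <- moments_at(nodes, u)
      ll <- ll + sum(stats::dnorm(cs$eggs_cum[ti == u], mo$mean,
                                  sqrt(mo$var + var_floor), log = TRUE))
    }
  }
  lg <- table[table$mode == "longitudinal", ]
  if (nrow(lg) > 0) {
    for (id in unique(lg$individual_id)) {
      rec <- lg[lg$individual_id == id, ]
      rec <- rec[order(rec$time_h), ]
      ti <- match(rec$time_h, times)
      mo <- moments_at(nodes, ti[1])
      ll <- ll + stats::dnorm(rec$eggs_cum[1], mo$mean,
                              sqrt(mo$var + var_floor), log = TRUE)
      if (nrow(rec) > 1) {
        for (k in 2:nrow(rec)) {
          dv <- nodes$E[, ti[k]] - nodes$E[, ti[k - 1]]
          m <- sum(nodes$w * dv)
          v <- max(sum(nodes$w * dv^2) - m^2, 0)
          ll <- ll + stats::dnorm(rec$eggs_cum[k] - rec$eggs_cum[k - 1],
                                  m, sqrt(v + var_floor), log = TRUE)
        }
      }
    }
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}
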