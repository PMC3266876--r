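#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample
#' mean; the scale-free measure used to compare between-individual
#' variability of brood sizes across temperatures.
#'
#' @param x numeric vector with positive mean.
#' @return `sd(x) / mean(x)`.
#' @examples
#' coef_variation(c(100, 200, 300)) # 0.5
#' @export
coef_variation <- function(x) {
  if (length(x) < 2 || any(!is.finite(x))) stop("need >= 2 finite values")
  m <- mean(x)
  if (m <= 0) stop("coefficient of variation requires a positive mean")
  stats::sd(x) / m
}

#' Permutation test for equality of coefficients of variation
#'
#' Tests whether two brood-size samples share the same coefficient of
#' variation. The statistic is `d = |CoV_A - CoV_B|`; under the null
#' the group labels are exchangeable, so the two samples are pooled
#' and relabelled `n_resamples` times. The two-sided p-value is the
#' fraction of resampled statistics at least as extreme as `d`, with
#' the +1 small-sample correction, so `p >= 1/(n_resamples + 1)`.
#'
#' @param a,b numeric brood-size vectors (length >= 2 each).
#' @param n_resamples number of relabelings (the study design uses
#'   1e6; resampling is chunked so memory stays bounded).
#' @param seed optional integer seed for the resampling.
#' @return An object of class `permutation_result`: list with
#'   `statistic` (d), `p_value`, `n_resamples`, `seed`.
#' @export
permutation_test_cov <- function(a, b, n_resamples = 1e6, seed = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  d_obs <- abs(coef_variation(a) - coef_variation(b))
  pool <- c(a, b)
  n <- length(pool)
  nA <- length(a)
  nB <- length(b)
  col_cv <- function(X, m) {
    cm <- colMeans(X)
    csd <- sqrt(pmax(colSums(X^2) - m * cm^2, 0) / (m - 1))
    csd / cm
  }
  n_extreme <- 0
  left <- n_resamples
  chunk_max <- 10000L
  while (left > 0) {
    nc <- as.integer(min(chunk_max, left))
    idx <- vapply(seq_len(nc), function(i) sample.int(n), integer(n))
    X <- matrix(pool[idx], nrow = n)
    d_perm <- abs(col_cv(X[seq_len(nA), , drop = FALSE], nA) -
                    col_cv(X[nA + seq_len(nB), , drop = FALSE], nB))
    n_extreme <- n_extreme + sum(d_perm >= d_obs - 1e-12)
    left <- left - nc
  }
  structure(list(statistic = d_obs,
                 p_value = (1 + n_extreme) / (n_resamples + 1),
                 n_resamples = n_resamples, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test on |CoV_A - CoV_B|: d = %.5g, p = %.4g (%g resamples)\n",
              x$statistic, x$p_value, x$n_resamples))
  invisible(x)
}

# One-sample KS distance between data and N(mu, sd).
ks_normal_stat <- function(x, mu, sd) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mu, sd)
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' Parametric-bootstrap test of single-normal adequacy
#'
#' Kolmogorov-Smirnov distance between the sample and a normal with
#' parameters estimated from the same sample. Because estimating the
#' parameters makes the naive KS test anti-conservative, the null
#' distribution of the statistic is obtained by a parametric bootstrap
#' (Lilliefors-style): simulate from the fitted normal, re-estimate,
#' recompute the statistic.
#'
#' @param x numeric sample (length >= 4).
#' @param n_boot number of bootstrap replicates.
#' @param seed optional integer seed.
#' @return List with `statistic`, `p_value`
#'   (`(1 + #\{D* >= D\}) / (n_boot + 1)`), `n_boot`, `mean`, `sd`.
#' @export
ks_normality_test <- function(x, n_boot = 999, seed = NULL) {
  if (length(x) < 4 || any(!is.finite(x))) stop("need >= 4 finite values")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  D <- ks_normal_stat(x, mu, s)
  D_boot <- vapply(seq_len(n_boot), function(i) {
    y <- stats::rnorm(n, mu, s)
    ks_normal_stat(y, mean(y), stats::sd(y))
  }, numeric(1))
  list(statistic = D, p_value = (1 + sum(D_boot >= D)) / (n_boot + 1),
       n_boot = n_boot, mean = mu, sd = s)
}
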