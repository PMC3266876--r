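#' Kinetic parameters of the gamete-flow model
#'
#' Container for the rate constants of the mass-action model of
#' hermaphrodite reproduction. The full model tracks developed oocytes
#' `O`, active sperm `S_a`, laid eggs `E` and dead sperm `S_d`:
#' oocytes are generated at rate `k_g - k_s * O` (constant production
#' relaxing towards the gonad carrying capacity `k_g / k_s`), ovulation
#' and fertilization proceed by mass action at rate `k_o * O * S_a`
#' (each egg consumes one sperm), and sperm die at rate `k_d * S_a`.
#' Under the quasi-steady-state (QSS) reduction the egg-laying rate
#' collapses to the saturating form `k_max * S_a / (k_hat + S_a)` with
#' `k_max = k_g` and `k_hat = k_s / k_o`; both derived constants are
#' stored alongside the primitive ones.
#'
#' The parameter set can be built either from the full-model constants
#' `(k_g, k_s, k_o)` or from the QSS pair `(k_max, k_hat)`. In the
#' latter case the oocyte relaxation scale `k_s` is a free choice (it
#' does not affect QSS dynamics); `oocyte_relax` sets it.
#'
#' @param k_g oocyte generation rate constant (oocytes/h).
#' @param k_s gonad carrying-capacity relaxation constant (1/h).
#' @param k_o ovulation rate constant (1/(sperm h), mass-action form).
#' @param k_d sperm death rate constant (1/h).
#' @param k_do oocyte death rate constant (1/h); 0 in the parsimonious model.
#' @param k_max intrinsic maximum oogenesis rate (eggs/h), QSS form.
#' @param k_hat sperm half-saturation constant (sperm), QSS form.
#' @param oocyte_relax value used for `k_s` when constructing from
#'   `(k_max, k_hat)`; larger values put the full model deeper in the
#'   QSS regime.
#'
#' @return An object of class `kinetic_params`: a list with elements
#'   `k_g`, `k_s`, `k_o`, `k_d`, `k_do`, `k_max`, `k_hat`.
#' @examples
#' kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001, k_d = 0.01)
#' kinetic_params(k_max = 7.5, k_hat = 100, k_d = 0.01)
#' @export
kinetic_params <- function(k_g = NULL, k_s = NULL, k_o = NULL, k_d = 0,
                           k_do = 0, k_max = NULL, k_hat = NULL,
                           oocyte_relax = 1) {
  if (is.null(k_g)) {
    if (is.null(k_max) || is.null(k_hat))
      stop("supply either (k_g, k_s, k_o) or (k_max, k_hat)")
    if (k_hat <= 0) stop("k_hat must be positive")
    k_g <- k_max
    k_s <- oocyte_relax
    k_o <- k_s / k_hat
  }
  if (is.null(k_s) || is.null(k_o))
    stop("full parameterization requires k_g, k_s and k_o")
  vals <- c(k_g = k_g, k_s = k_s, k_o = k_o, k_d = k_d, k_do = k_do)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and >= 0")
  p <- list(k_g = k_g, k_s = k_s, k_o = k_o, k_d = k_d, k_do = k_do,
            k_max = k_g, k_hat = if (k_o > 0) k_s / k_o else Inf)
  if (!is.null(k_max) && abs(k_max - p$k_max) > 1e-8 * max(1, k_max))
    stop("inconsistent k_max: QSS mapping requires k_max = k_g")
  if (!is.null(k_hat) && is.finite(p$k_hat) &&
      abs(k_hat - p$k_hat) > 1e-8 * max(1, k_hat))
    stop("inconsistent k_hat: QSS mapping requires k_hat = k_s / k_o")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Gamete-flow kinetic parameters\n")
  cat(sprintf("  k_g  = %.6g oocytes/h   k_s = %.6g /h   k_o = %.6g /(sperm h)\n",
              x$k_g, x$k_s, x$k_o))
  cat(sprintf("  k_d  = %.6g /h   k_do = %.6g /h\n", x$k_d, x$k_do))
  cat(sprintf("  QSS: k_max = %.6g eggs/h   k_hat = %.6g sperm\n",
              x$k_max, x$k_hat))
  invisible(x)
}

stopifnot_params <- function(p) {
  if (!inherits(p, "kinetic_params")) stop("`p` must be a kinetic_params object")
  invisible(p)
}

#' Exponential temperature laws for the model parameters
#'
#' Over the narrow physiological range (20-30 degrees C) each
#' temperature-sensitive quantity is modelled as `exp(a + b * T)`:
#' the oogenesis capacity `k_max`, the sperm death rate `k_d`, and the
#' non-robust fraction `delta` (clipped at `delta_cap`). The sperm
#' half-saturation constant `k_hat` is held fixed across temperature.
#'
#' @param k_max,k_d,delta numeric length-2 vectors `c(a, b)` of
#'   log-linear coefficients for each law.
#' @param k_hat sperm half-saturation constant (sperm), temperature
#'   independent.
#' @param delta_cap upper clip for `delta` (probability).
#' @param range validity range of the laws in degrees C; evaluation
#'   outside it is flagged as extrapolation.
#' @return An object of class `temperature_law`.
#' @seealso [params_at_temperature()], [default_temperature_law()]
#' @export
temperature_law <- function(k_max, k_d, delta, k_hat = 100,
                            delta_cap = 1, range = c(20, 30)) {
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)))
      stop(sprintf("law `%s` must be a finite numeric c(a, b)", nm))
    v <- unname(v)
    names(v) <- c("a", "b")
    v
  }
  if (!is.numeric(k_hat) || k_hat <= 0) stop("k_hat must be positive")
  structure(list(k_max = chk(k_max, "k_max"), k_d = chk(k_d, "k_d"),
                 delta = chk(delta, "delta"), k_hat = k_hat,
                 delta_cap = delta_cap, range = sort(range)),
            class = "temperature_law")
}

#' @export
print.temperature_law <- function(x, ...) {
  cat("Exponential temperature laws, parameter(T) = exp(a + b T)\n")
  for (nm in c("k_max", "k_d", "delta"))
    cat(sprintf("  %-5s: a = %9.4f  b = %8.4f\n", nm, x[[nm]]["a"], x[[nm]]["b"]))
  cat(sprintf("  k_hat = %g sperm (fixed); delta clipped at %g; range %g-%g C\n",
              x$k_hat, x$delta_cap, x$range[1], x$range[2]))
  invisible(x)
}

#' Default temperature law used by the simulator
#'
#' Calibrated so that mean broods are roughly 300, 200, 27, 10 and <5
#' eggs at 20, 25, 28, 29 and 30 degrees C, with the non-robust
#' fraction negligible at 25 degrees C and below, about 0.25 at 28 and
#' 0.6 at 29 degrees C, and reproduction effectively ceasing at 30.
#'
#' @return A [temperature_law()] object.
#' @export
default_temperature_law <- function() {
  temperature_law(
    k_max = c(1.16396, 0.04250),   # 7.5 eggs/h at 20 C
    k_d   = c(-30.40844, 1.05991), # 1e-4 /h at 20 C, 0.02 at 25 C
    delta = c(-25.89961, 0.87547), # 0.25 at 28 C, 0.6 at 29 C
    k_hat = 100
  )
}

#' Evaluate the temperature laws at a given temperature
#'
#' @param temp_C temperature in degrees C.
#' @param law a [temperature_law()] object.
#' @param oocyte_relax passed to [kinetic_params()] (full-model
#'   relaxation scale; irrelevant for QSS dynamics).
#' @return A list with elements `params` (a [kinetic_params()] object
#'   at `temp_C`), `delta` (the non-robust fraction, clipped to
#'   \[0, delta_cap\]), `temp_C`, and `extrapolated` (TRUE with a
#'   warning when `temp_C` lies outside the law's validity range).
#' @examples
#' params_at_temperature(25, default_temperature_law())
#' @export
params_at_temperature <- function(temp_C, law, oocyte_relax = 1) {
  if (!inherits(law, "temperature_law")) stop("`law` must be a temperature_law")
  if (!is.numeric(temp_C) || length(temp_C) != 1 || !is.finite(temp_C))
    stop("`temp_C` must be a single finite number")
  extrap <- temp_C < law$range[1] || temp_C > law$range[2]
  if (extrap)
    warning(sprintf("temperature %.3g C outside law validity range [%g, %g]; extrapolating",
                    temp_C, law$range[1], law$range[2]))
  ev <- function(cf) exp(cf["a"] + cf["b"] * temp_C)
  delta <- min(max(unname(ev(law$delta)), 0), law$delta_cap)
  list(params = kinetic_params(k_max = unname(ev(law$k_max)), k_hat = law$k_hat,
                               k_d = unname(ev(law$k_d)),
                               oocyte_relax = oocyte_relax),
       delta = delta, temp_C = temp_C, extrapolated = extrap)
}
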