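#' Elementary rates of the gamete-flow model
#'
#' `generation_rate()` is the net oocyte production term
#' `k_g - k_s * O`: constant de-novo generation relaxing towards the
#' gonad carrying capacity `k_g / k_s` (it may be negative above
#' capacity; it is the ODE right-hand side, not a flux into a sink).
#' `ovulation_rate()` is the mass-action ovulation/fertilization flux
#' `k_o * O * S_a` (sperm signal MSP couples oocyte maturation and
#' ovulation to sperm presence, hence the product form), and
#' `sperm_death_rate()` is `k_d * S_a`.
#'
#' @param O developed oocyte count (>= 0, continuous).
#' @param S_a active sperm count (>= 0, continuous).
#' @param p a [kinetic_params()] object.
#' @return The requested rate (per hour).
#' @examples
#' p <- kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001, k_d = 0.01)
#' generation_rate(50, p)   # 5
#' ovulation_rate(20, 300, p) # 6
#' sperm_death_rate(300, p)   # 3
#' @export
generation_rate <- function(O, p) {
  stopifnot_params(p)
  if (any(!is.finite(O)) || any(O < 0)) stop("O must be finite and >= 0")
  p$k_g - p$k_s * O
}

#' @rdname generation_rate
#' @export
ovulation_rate <- function(O, S_a, p) {
  stopifnot_params(p)
  if (any(!is.finite(O)) || any(O < 0)) stop("O must be finite and >= 0")
  if (any(!is.finite(S_a)) || any(S_a < 0)) stop("S_a must be finite and >= 0")
  p$k_o * O * S_a
}

#' @rdname generation_rate
#' @export
sperm_death_rate <- function(S_a, p) {
  stopifnot_params(p)
  if (any(!is.finite(S_a)) || any(S_a < 0)) stop("S_a must be finite and >= 0")
  p$k_d * S_a
}

#' Quasi-steady-state oocyte pool and egg-laying rate
#'
#' The oocyte pool relaxes quickly relative to sperm depletion, so it
#' is held at the root of `generation_rate - ovulation_rate = 0`:
#' `O* = k_g / (k_s + k_o * S_a)`. Substituting into the ovulation flux
#' gives the saturating egg-laying rate
#' `k_max * S_a / (k_hat + S_a)` with `k_max = k_g`, `k_hat = k_s/k_o`.
#'
#' @inheritParams generation_rate
#' @return `qss_oocyte_count()`: the equilibrium oocyte pool;
#'   `qss_egg_rate()`: the egg-laying rate (eggs/h).
#' @examples
#' p <- kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001)
#' qss_oocyte_count(300, p) # 25
#' qss_egg_rate(300, p)     # 7.5
#' @export
qss_oocyte_count <- function(S_a, p) {
  stopifnot_params(p)
  if (any(!is.finite(S_a)) || any(S_a < 0)) stop("S_a must be finite and >= 0")
  denom <- p$k_s + p$k_o * S_a
  if (any(denom == 0)) stop("degenerate parameters: k_s = 0 with S_a = 0")
  p$k_g / denom
}

#' @rdname qss_oocyte_count
#' @export
qss_egg_rate <- function(S_a, p) {
  stopifnot_params(p)
  if (any(!is.finite(S_a)) || any(S_a < 0)) stop("S_a must be finite and >= 0")
  p$k_max * S_a / (p$k_hat + S_a)
}

#' Map the oocyte-death model onto the parsimonious model
#'
#' Adding an explicit oocyte-death channel (rate `k_do * O`, sink
#' `O_d`) changes the oocyte balance to
#' `dO/dt = k_g - (k_s + k_do) * O - k_o * O * S_a`, which is the
#' parsimonious model with `k_s` replaced by `k_s + k_do` (and hence a
#' larger half-saturation constant `k_hat`). This function returns
#' those remapped parameters; egg and sperm trajectories of the two
#' models are identical.
#'
#' @param p a [kinetic_params()] object, possibly with `k_do > 0`.
#' @return A [kinetic_params()] object with `k_do = 0` and
#'   `k_s' = k_s + k_do`.
#' @export
with_oocyte_death <- function(p) {
  stopifnot_params(p)
  kinetic_params(k_g = p$k_g, k_s = p$k_s + p$k_do, k_o = p$k_o,
                 k_d = p$k_d, k_do = 0)
}
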