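#' Transition-state-theory rate from a free energy barrier
#'
#' Eyring equation: `k = transmission * (k_B T / h) * exp(-barrier / (R T))`
#' with CODATA constants and R in kcal/(mol K). The temperature is always
#' echoed in the result because a barrier-to-rate conversion is meaningless
#' without it; the default is 298.15 K.
#'
#' @param barrier activation free energy, kcal/mol.
#' @param temperature K (> 0).
#' @param transmission transmission coefficient (default 1, plain TST).
#' @return a `rate_result`: list with `barrier`, `temperature`, `rate` (s^-1),
#'   `transmission`.
#' @examples
#' eyring_rate(21.6)$rate        # ~9.1e-4 s^-1
#' eyring_rate(21.6, 310)$rate   # ~3.8e-3 s^-1
#' @export
eyring_rate <- function(barrier, temperature = 298.15, transmission = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  prefactor <- .KB_SI * temperature / .H_SI
  rate <- transmission * prefactor * exp(-barrier / (.R_KCAL * temperature))
  structure(list(barrier = barrier, temperature = temperature, rate = rate,
                 transmission = transmission),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k = %.4g s^-1 (barrier %.3f kcal/mol at %.2f K, transmission %g)\n",
              x$rate, x$barrier, x$temperature, x$transmission))
  invisible(x)
}

#' Apparent activation free energy from a rate constant
#'
#' Exact inverse of [eyring_rate] (transmission 1):
#' `barrier = -R T log(k h / (k_B T))`.
#'
#' @param rate s^-1 (> 0).
#' @param temperature K.
#' @return kcal/mol.
#' @export
barrier_from_rate <- function(rate, temperature = 298.15) {
  if (any(rate <= 0)) stop("rate must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  -.R_KCAL * temperature * log(rate * .H_SI / (.KB_SI * temperature))
}

#' Gross-Butler proton inventory curve
#'
#' Rate constant as a function of the D2O atom fraction `n` for a transition
#' state with one fractionation factor per exchangeable site:
#' `k_n = k0 * prod_i (1 - n + n * phi_i)`. With exactly one site in flight
#' the curve is a straight line — the diagnostic that the rate-limiting
#' transition state moves a single proton; two or more sites curve it
#' downwards. The linearity statistic is the maximum absolute deviation of
#' the curve from its chord, relative to `k0`.
#'
#' @param k0 rate in pure H2O, s^-1 (> 0).
#' @param phis fractionation factors, one per site (> 0); the solvent kinetic
#'   isotope effect of a one-site model is `1/phi`.
#' @param n_points grid size over `n` in `[0, 1]`.
#' @return a `proton_inventory`: `curve` (tibble `n`, `k_n`), `phis`, `k0`,
#'   `linearity`.
#' @examples
#' gross_butler(1e-3, 1 / 1.4)$linearity  # exactly 0 (one proton in flight)
#' @export
gross_butler <- function(k0, phis, n_points = 21) {
  if (k0 <= 0) stop("k0 must be > 0")
  if (any(phis <= 0)) stop("fractionation factors must be > 0")
  n <- seq(0, 1, length.out = n_points)
  k_n <- k0 * vapply(n, function(ni) prod(1 - ni + ni * phis), numeric(1))
  chord <- k_n[1] + n * (k_n[n_points] - k_n[1])
  structure(list(curve = tibble::tibble(n = n, k_n = k_n),
                 phis = phis, k0 = k0,
                 linearity = max(abs(k_n - chord)) / k0),
            class = "proton_inventory")
}

#' @export
print.proton_inventory <- function(x, ...) {
  cat(sprintf("proton inventory: %d site(s), k_H/k_D = %.3f, chord deviation %.3g x k0\n",
              length(x$phis), 1 / prod(x$phis), x$linearity))
  invisible(x)
}

#' Semiclassical H/D kinetic isotope effect
#'
#' Harmonic zero-point-energy model for the isotope effect of a proton whose
#' stretching frequency drops from `gs_frequency` in the ground state to
#' `ts_frequency` at the transition state (0 for a fully lost stretch).
#' Deuterium frequencies are idealised as `nu_H / sqrt(2)` (reduced-mass
#' scaling; real X-H/X-D ratios are ~1.35-1.41), giving
#' `KIE = exp( (nu_GS - nu_TS) * (1 - 1/sqrt(2)) * hc / (2 k_B T) )`
#' with the thermal energy expressed in cm^-1 (207.22 cm^-1 at 298.15 K).
#'
#' @param gs_frequency ground-state stretch, cm^-1 (>= 0).
#' @param ts_frequency transition-state stretch, cm^-1 (>= 0). Values above
#'   `gs_frequency` are permitted (inverse KIE) but flagged.
#' @param temperature K.
#' @return a `kie_model`: list with the inputs, `kie` and `inverse` flag.
#' @examples
#' semiclassical_kie(3000, 2524)$kie  # ~1.4, one proton in flight
#' @export
semiclassical_kie <- function(gs_frequency, ts_frequency,
                              temperature = 298.15) {
  if (gs_frequency < 0 || ts_frequency < 0) stop("frequencies must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  kT_cm <- .KB_SI * temperature / (.H_SI * .C_CM)
  dnu <- gs_frequency - ts_frequency
  kie <- exp(dnu * (1 - 1 / sqrt(2)) / (2 * kT_cm))
  inverse <- ts_frequency > gs_frequency
  if (inverse)
    warning("ts_frequency exceeds gs_frequency: inverse isotope effect")
  structure(list(gs_frequency = gs_frequency, ts_frequency = ts_frequency,
                 temperature = temperature, kie = kie, inverse = inverse),
            class = "kie_model")
}

#' @export
print.kie_model <- function(x, ...) {
  cat(sprintf("semiclassical KIE = %.3f (nu_GS %.0f -> nu_TS %.0f cm^-1 at %.2f K)%s\n",
              x$kie, x$gs_frequency, x$ts_frequency, x$temperature,
              if (x$inverse) " [inverse]" else ""))
  invisible(x)
}
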