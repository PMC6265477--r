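#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)` (Levenberg-Marquardt),
#' initialised from a Hanes-Woolf linearisation (`S/v` against `S`), with
#' standard errors from the asymptotic covariance of the fit and
#' `kcat = Vmax / E0` (fully active enzyme assumed). A fitted `Km` outside
#' `[min(S)/50, 50 max(S)]` is flagged ill-determined.
#'
#' @param dataset a `kinetics_sample` (see [generate_mm_kinetics]) or a data
#'   frame with columns `substrate_uM` and `velocity_uM_per_s`.
#' @param E0 enzyme concentration in uM (taken from the sample if present).
#' @return an `mm_fit`: list with `Vmax`, `Km`, `kcat`, standard errors
#'   (`Vmax_se`, `Km_se`, `kcat_se`), `ill_determined`, and the underlying
#'   `fit` object.
#' @examples
#' ks <- generate_mm_kinetics(11.85e-3, 3.12, 0.1)
#' fit_michaelis_menten(ks)$kcat
#' @export
fit_michaelis_menten <- function(dataset, E0 = NULL) {
  if (inherits(dataset, "kinetics_sample")) {
    df <- dataset$data
    if (is.null(E0)) E0 <- dataset$E0
  } else {
    df <- as.data.frame(dataset)
  }
  if (is.null(E0) || E0 <= 0) stop("E0 must be supplied and > 0")
  S <- df$substrate_uM
  v <- df$velocity_uM_per_s
  if (length(unique(S)) < 4)
    stop("need at least 4 distinct substrate concentrations")
  # Hanes-Woolf: S/v = S/Vmax + Km/Vmax
  use <- v > 0
  hw <- lm(I(S[use] / v[use]) ~ S[use])
  Vmax0 <- unname(1 / coef(hw)[2])
  Km0 <- unname(coef(hw)[1] * Vmax0)
  if (!is.finite(Vmax0) || Vmax0 <= 0) Vmax0 <- max(v)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = Vmax0, Km = Km0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      resid <- v - Vmax0 * S / (Km0 + S)
      stop("Michaelis-Menten fit failed to converge (", conditionMessage(e),
           "); residuals at start: ", paste(signif(resid, 3), collapse = ", "))
    })
  cf <- summary(fit)$coefficients
  Vmax <- cf["Vmax", "Estimate"]; Km <- cf["Km", "Estimate"]
  structure(list(
    Vmax = Vmax, Km = Km, kcat = Vmax / E0,
    Vmax_se = cf["Vmax", "Std. Error"], Km_se = cf["Km", "Std. Error"],
    kcat_se = cf["Vmax", "Std. Error"] / E0, E0 = E0,
    ill_determined = Km < min(S) / 50 || Km > 50 * max(S),
    fit = fit),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("kcat = %.4g +/- %.2g s^-1, Km = %.4g +/- %.2g uM%s\n",
              x$kcat, x$kcat_se, x$Km, x$Km_se,
              if (x$ill_determined) " [Km ill-determined]" else ""))
  invisible(x)
}

#' Measured single-cleavage substrate parameters
#'
#' The kinetic parameters of human Usb1 for the four single-cleavage
#' substrates (a 2'-deoxyuridine at the n-2 position restricts the enzyme to
#' one cut; the 'd' prefix marks the deoxy residue). kcat is on the 10^-3
#' s^-1 scale, Km in uM, with standard errors from nonlinear regression.
#'
#' @return a tibble: `name`, `kcat_e3`, `kcat_se_e3`, `Km_uM`, `Km_se_uM`.
#' @export
usb1_substrate_table <- function() {
  tibble::tibble(
    name = c("UAUUUdUUU", "UAUUUdUAU", "UAUUUdUUA", "UAUUUdUAA"),
    kcat_e3 = c(1.31, 1.07, 11.85, 8.78),
    kcat_se_e3 = c(0.02, 0.05, 0.61, 0.48),
    Km_uM = c(7.58, 9.75, 3.12, 7.17),
    Km_se_uM = c(0.38, 1.22, 0.56, 1.21))
}

#' Catalytic efficiency table
#'
#' Computes `kcat/Km` on the 10^3 M^-1 s^-1 scale (numerically
#' `kcat[10^-3 s^-1] / Km[uM]`) and efficiencies relative to a reference
#' substrate, from unrounded quotients. Display columns round the efficiency
#' to 2 decimals and the relative value to 2 significant figures.
#'
#' @param rows a tibble like [usb1_substrate_table] (`name`, `kcat_e3`,
#'   `Km_uM`, optional standard errors).
#' @param reference_name row whose efficiency defines `relative = 1`.
#' @return an `efficiency_table` tibble with `efficiency`, `relative` and
#'   their display columns.
#' @examples
#' efficiency_table(usb1_substrate_table(), "UAUUUdUUU")
#' @export
efficiency_table <- function(rows, reference_name) {
  rows <- tibble::as_tibble(rows)
  if (anyDuplicated(rows$name)) stop("duplicate substrate names")
  if (!reference_name %in% rows$name)
    stop("reference substrate not present: ", reference_name)
  if (any(rows$kcat_e3 <= 0 | rows$Km_uM <= 0))
    stop("kcat and Km must be positive")
  eff <- rows$kcat_e3 / rows$Km_uM # 10^3 M^-1 s^-1
  rel <- eff / eff[rows$name == reference_name]
  out <- rows
  out$efficiency <- eff
  out$relative <- rel
  out$efficiency_display <- round(eff, 2)
  out$relative_display <- signif(rel, 2)
  class(out) <- c("efficiency_table", class(out))
  out
}
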