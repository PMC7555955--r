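#' Mean specific energy deposited per event in a spherical site
#'
#' Converts a lineal-energy (or LET) descriptor of a radiation into the mean
#' specific energy imparted by a single event to a spherical site of the
#' given radius, via the geometric relation
#' \deqn{\bar z = \frac{0.1602\, y}{\rho \pi r^2}}
#' with `y` in keV/um, `r` in um, `rho` in g/cm^3 and the result in Gy.
#' The constant 0.1602 is the exact keV-to-Gy conversion for a micrometre-
#' scale water mass; at the canonical mammalian nucleus radius of 3.0 um it
#' yields the convenience coefficient 0.0057 Gy per keV/um (2 s.f.), i.e.
#' `zF_n ~ 0.0057 * LET`.
#'
#' Used at the nucleus scale (radius `rn`, frequency-average `yF`) this gives
#' `zF_n`, the dose threshold below which at most one event per domain is
#' expected; with the dose-average `yD` it gives `zD_n`.  At the domain scale
#' (radius `rd`) it gives the domain dose-mean specific energy `zD`.
#'
#' @param y Lineal energy or LET in keV/um (vectorised, each `>= 0`).
#' @param radius Site radius in um (`> 0`).
#' @param density Site density in g/cm^3 (default 1.0, liquid water).
#' @return Specific energy per event in Gy, same length as `y`.
#' @examples
#' specific_energy_per_event(86, 3.0)    # ~0.49 Gy (Ar ions, nucleus)
#' specific_energy_per_event(442, 4.5)   # ~1.11 Gy (Fe ions, enlarged nucleus)
#' @export
specific_energy_per_event <- function(y, radius, density = 1.0) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0)) {
    abort("`y` must be finite and >= 0 (keV/um).")
  }
  .assert_scalar_num(radius, "radius", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(density, "density", lower = 0, strict_lower = TRUE)
  KEV_PER_UM3_TO_GY * y / (density * pi * radius^2)
}

#' Domain radius from the X-ray alpha/beta ratio
#'
#' Empirical relation tying the MKM domain radius to the photon
#' linear-quadratic ratio of the cell line:
#' \deqn{r_d\,[\mu m] = \left(\frac{0.194}{(\alpha/\beta)_x\,[Gy]}\right)^{1/3}}
#' assuming a nucleus radius of 3.0 um.  Note the ratio appears in the
#' denominator: the relation is strictly decreasing in `(alpha/beta)_x`
#' (radiosensitive lines with small ratios have larger pairing distances).
#' A variant with the ratio as a multiplier circulates in print but does not
#' reproduce published domain radii; only the division form is implemented.
#'
#' @param alpha_x Photon linear coefficient in 1/Gy (`> 0`).
#' @param beta_x Photon quadratic coefficient in 1/Gy^2 (`> 0`).
#' @return Domain radius in um.
#' @examples
#' domain_radius_from_alpha_beta(0.195, 0.026)  # ~0.295 um
#' @export
domain_radius_from_alpha_beta <- function(alpha_x, beta_x) {
  .assert_scalar_num(alpha_x, "alpha_x", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(beta_x, "beta_x", lower = 0, strict_lower = TRUE)
  (0.194 / (alpha_x / beta_x))^(1 / 3)
}

#' Combined per-track nucleus specific energy of a radiation mixture
#'
#' When several radiations are delivered simultaneously, the number of tracks
#' per unit dose adds as `sum(w_i / zF_n_i)`, so the combined mean specific
#' energy per track is the dose-weighted harmonic mean
#' \deqn{z_{F,n,c} = \left(\sum_i \omega_i / z_{F,n,i}\right)^{-1}.}
#' If any component with positive weight has `zF_n = 0` (an X-ray reference
#' field contributes effectively infinitely many tracks per Gy) the combined
#' value is 0: the mixture is Poisson-like from the origin.
#'
#' @param weights Dose fractions, `>= 0`, summing to 1 (tolerance 1e-9).
#' @param zF_n_values Per-component `zF_n` in Gy, `>= 0`, same length.
#' @return Combined `zF_n` in Gy; bounded by the component min and max.
#' @examples
#' combined_zF_n(c(0.5, 0.5), c(0.49, 0.049))
#' @export
combined_zF_n <- function(weights, zF_n_values) {
  if (length(weights) != length(zF_n_values)) {
    abort("`weights` and `zF_n_values` must have the same length.")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("`weights` must be finite and >= 0.")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must sum to 1.")
  }
  if (any(!is.finite(zF_n_values)) || any(zF_n_values < 0)) {
    abort("`zF_n_values` must be finite and >= 0.")
  }
  if (any(weights > 0 & zF_n_values == 0)) {
    return(0)
  }
  active <- weights > 0
  1 / sum(weights[active] / zF_n_values[active])
}

#' Cell-line model: geometry and intrinsic LQ coefficients
#'
#' Bundles the intrinsic (microscopic) linear-quadratic coefficients of the
#' cell line with its MKM geometry.  `alpha0` and `beta0` are the photon-fit
#' LQ parameters; `rn` is the nucleus radius and `rd` the domain radius, the
#' maximum distance over which two sublethal lesions can pair into a lethal
#' one.  When `rd` is omitted it is derived from `(alpha0/beta0)` via
#' [domain_radius_from_alpha_beta()].
#'
#' @param alpha0 Intrinsic linear coefficient, 1/Gy (`>= 0`).
#' @param beta0 Intrinsic quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @param rn Nucleus radius in um (default 3.0, average mammalian nucleus).
#' @param rd Domain radius in um, `0 < rd < rn`; `NULL` to derive from
#'   `(alpha0/beta0)`.
#' @param density Density in g/cm^3 (default 1.0, liquid water).
#' @return An object of class `cell_model` (named list).
#' @examples
#' cell_model(0.195, 0.026)          # V79, Ar experiment; rd derived
#' cell_model(0.18, 0.016, rn = 4.5) # V79, Fe experiment, enlarged nucleus
#' @export
cell_model <- function(alpha0, beta0, rn = 3.0, rd = NULL, density = 1.0) {
  .assert_scalar_num(alpha0, "alpha0", lower = 0)
  .assert_scalar_num(beta0, "beta0", lower = 0)
  .assert_scalar_num(rn, "rn", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(density, "density", lower = 0, strict_lower = TRUE)
  if (is.null(rd)) {
    if (alpha0 <= 0 || beta0 <= 0) {
      abort("`rd` can only be derived when both `alpha0` and `beta0` are > 0.")
    }
    rd <- domain_radius_from_alpha_beta(alpha0, beta0)
  }
  .assert_scalar_num(rd, "rd", lower = 0, strict_lower = TRUE)
  if (rd >= rn) {
    abort("`rd` must be smaller than the nucleus radius `rn`.")
  }
  structure(
    list(alpha0 = alpha0, beta0 = beta0, rn = rn, rd = rd, density = density),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> alpha0 = %g /Gy, beta0 = %g /Gy^2, rn = %g um, rd = %g um, density = %g g/cm^3\n",
    x$alpha0, x$beta0, x$rn, x$rd, x$density
  ))
  invisible(x)
}

#' Microdosimetric description of one radiation
#'
#' Derives the specific-energy parameters that drive the survival model from
#' a lineal-energy (LET) descriptor and a cell geometry:
#' * `zF_n` — mean specific energy per event in the nucleus, from `yF` and
#'   `rn`; the dose threshold of the initial linear survival segment,
#' * `zD_n` — dose-average specific energy per event in the nucleus, from
#'   `yD` and `rn`; drives the overkill saturation factor,
#' * `zD`  — dose-average specific energy per event in a domain, from `yD`
#'   and `rd`; augments the effective linear coefficient.
#'
#' `yD` defaults to `yF` (monoenergetic track-segment approximation).  Any of
#' the derived quantities can be overridden directly, e.g. with values from
#' measured microdosimetric spectra.  Use [xray_quality()] for the low-LET
#' reference field, which is modelled with all specific energies zero.
#'
#' @param label Radiation label (text).
#' @param yF Frequency-average lineal energy in keV/um; equals the LET of a
#'   monoenergetic beam, the track-average LET of a composed beam.
#' @param cell A [cell_model()]; required unless all of `zF_n`, `zD_n`, `zD`
#'   are supplied.
#' @param yD Dose-average lineal energy in keV/um (default `yF`); must be
#'   `>= yF`.
#' @param zF_n,zD_n,zD Optional direct overrides in Gy.
#' @return An object of class `radiation_quality` (named list).
#' @examples
#' v79 <- cell_model(0.195, 0.026)
#' radiation_quality("Ar", yF = 86, cell = v79)
#' @export
radiation_quality <- function(label, yF, cell = NULL, yD = yF,
                              zF_n = NULL, zD_n = NULL, zD = NULL) {
  .assert_scalar_num(yF, "yF", lower = 0)
  .assert_scalar_num(yD, "yD", lower = 0)
  if (yD < yF) {
    abort("`yD` must be >= `yF` (dose average dominates frequency average).")
  }
  need_cell <- is.null(zF_n) || is.null(zD_n) || is.null(zD)
  if (need_cell) {
    if (!inherits(cell, "cell_model")) {
      abort("`cell` (a cell_model) is required to derive specific energies.")
    }
    zF_n <- zF_n %||% specific_energy_per_event(yF, cell$rn, cell$density)
    zD_n <- zD_n %||% specific_energy_per_event(yD, cell$rn, cell$density)
    zD <- zD %||% specific_energy_per_event(yD, cell$rd, cell$density)
  }
  .assert_scalar_num(zF_n, "zF_n", lower = 0)
  .assert_scalar_num(zD_n, "zD_n", lower = 0)
  .assert_scalar_num(zD, "zD", lower = 0)
  if (zD_n < zF_n) {
    abort("`zD_n` must be >= `zF_n`.")
  }
  structure(
    list(label = as.character(label), yF = yF, yD = yD,
         zF_n = zF_n, zD_n = zD_n, zD = zD),
    class = "radiation_quality"
  )
}

#' Low-LET photon reference field
#'
#' X-rays deposit dose through very many sparse tracks, so per-event specific
#' energies are negligible: `zF_n = zD_n = zD = 0`.  The survival curve is
#' then plain linear-quadratic from the origin with saturation factor 1.
#'
#' @param label Radiation label (default `"X-ray"`).
#' @return A `radiation_quality` with all specific energies zero.
#' @export
xray_quality <- function(label = "X-ray") {
  radiation_quality(label, yF = 0, zF_n = 0, zD_n = 0, zD = 0)
}

#' @export
print.radiation_quality <- function(x, ...) {
  cat(sprintf(
    "<radiation_quality> %s: yF = %g keV/um, zF_n = %.4g Gy, zD_n = %.4g Gy, zD = %.4g Gy\n",
    x$label, x$yF, x$zF_n, x$zD_n, x$zD
  ))
  invisible(x)
}
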