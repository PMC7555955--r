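#' Effective linear-quadratic coefficients of one radiation component
#'
#' The low-dose linear coefficient a radiation contributes to a mixture is
#' its saturated MKM linear term, `alpha = (alpha0 + beta0*zD) * fs`; the
#' quadratic coefficient is the cell's intrinsic `beta0` (one photon-fit
#' `beta0` per experiment).  For an X-ray reference field this reduces to
#' `(alpha0, beta0)` exactly.
#'
#' @param cell A [cell_model()].
#' @param rad A [radiation_quality()].
#' @return A one-row tibble with columns `label`, `alpha`, `beta`.
#' @export
component_lq <- function(cell, rad) {
  fs <- .fs_for(cell, rad)
  tibble(
    label = rad$label,
    alpha = (cell$alpha0 + cell$beta0 * rad$zD) * fs,
    beta = cell$beta0
  )
}

#' Mixed-field linear-quadratic coefficients (dual radiation action)
#'
#' Under the theory of dual radiation action, sublethal lesions from the
#' two radiations pair across components, producing a cross term
#' `2*sqrt(beta_hi*beta_lo)*D_hi*D_lo`.  The mixture then behaves as a
#' single LQ field with
#' \deqn{\alpha_c = \sum_i \omega_i \alpha_i, \qquad
#'       \beta_c = \left(\sum_i \omega_i \sqrt{\beta_i}\right)^2.}
#' (The radical forms; radical-free variants seen in print are not
#' dimensionally consistent in Gy^-2.)  Generalises to any number of
#' components with dose fractions `omega`.
#'
#' @param alpha Per-component linear coefficients, 1/Gy (`>= 0`).
#' @param beta Per-component quadratic coefficients, 1/Gy^2 (`>= 0`).
#' @param omega Dose fractions, `>= 0`, summing to 1 (tolerance 1e-9).
#' @return A one-row tibble with columns `alpha_c`, `beta_c`.
#' @examples
#' tdra_mixture_lq(c(0.74, 0.195), c(0.026, 0.026), c(0.5, 0.5))
#' @export
tdra_mixture_lq <- function(alpha, beta, omega) {
  if (length(alpha) != length(beta) || length(alpha) != length(omega)) {
    abort("`alpha`, `beta` and `omega` must have the same length.")
  }
  if (any(!is.finite(alpha)) || any(alpha < 0)) {
    abort("`alpha` must be finite and >= 0.")
  }
  if (any(!is.finite(beta)) || any(beta < 0)) {
    abort("`beta` must be finite and >= 0.")
  }
  if (any(!is.finite(omega)) || any(omega < 0)) {
    abort("`omega` must be finite and >= 0.")
  }
  if (abs(sum(omega) - 1) > 1e-9) {
    abort("`omega` must sum to 1.")
  }
  tibble(
    alpha_c = sum(omega * alpha),
    beta_c = sum(omega * sqrt(beta))^2
  )
}

#' Specify a two-radiation exposure
#'
#' Pairs a high-LET and a low-LET radiation with their dose fractions and a
#' delivery schedule.  The low component must have the smaller per-track
#' nucleus specific energy (`zF_n`).
#'
#' @param high,low [radiation_quality()] objects; `low$zF_n <= high$zF_n`.
#' @param omega_high,omega_low Dose fractions, `>= 0`, summing to 1
#'   (simultaneous schedules).
#' @param schedule One of `"simultaneous_independent"`,
#'   `"simultaneous_combined"`, `"sequential_low_first"`,
#'   `"sequential_high_first"`.
#' @param first_course_dose First-course dose in Gy (sequential schedules
#'   only).
#' @return An object of class `mixture_spec`.
#' @examples
#' v79 <- cell_model(0.195, 0.026)
#' mixture_spec(radiation_quality("Ar", 86, v79), xray_quality(),
#'              omega_high = 0.5, schedule = "simultaneous_independent")
#' @export
mixture_spec <- function(high, low,
                         omega_high = 0.5, omega_low = 1 - omega_high,
                         schedule = c("simultaneous_independent",
                                      "simultaneous_combined",
                                      "sequential_low_first",
                                      "sequential_high_first"),
                         first_course_dose = NULL) {
  schedule <- match.arg(schedule)
  if (!inherits(high, "radiation_quality") ||
      !inherits(low, "radiation_quality")) {
    abort("`high` and `low` must be radiation_quality objects.")
  }
  if (low$zF_n > high$zF_n) {
    abort("`low$zF_n` must not exceed `high$zF_n` (component ordering).")
  }
  sequential <- startsWith(schedule, "sequential")
  if (sequential) {
    if (is.null(first_course_dose)) {
      abort("`first_course_dose` is required for a sequential schedule.")
    }
    .assert_scalar_num(first_course_dose, "first_course_dose", lower = 0)
  } else {
    .assert_scalar_num(omega_high, "omega_high", lower = 0)
    .assert_scalar_num(omega_low, "omega_low", lower = 0)
    if (abs(omega_high + omega_low - 1) > 1e-9) {
      abort("`omega_high` + `omega_low` must equal 1.")
    }
  }
  structure(
    list(high = high, low = low,
         omega_high = omega_high, omega_low = omega_low,
         schedule = schedule, first_course_dose = first_course_dose),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s + %s, schedule = %s\n",
              x$high$label, x$low$label, x$schedule))
  if (startsWith(x$schedule, "sequential")) {
    cat(sprintf("  first-course dose = %g Gy\n", x$first_course_dose))
  } else {
    cat(sprintf("  dose fractions: high %g, low %g\n",
                x$omega_high, x$omega_low))
  }
  invisible(x)
}

# Derived quantities shared by both simultaneous hypotheses.
.mixture_coefficients <- function(spec, cell) {
  hi <- component_lq(cell, spec$high)
  lo <- component_lq(cell, spec$low)
  mixed <- tdra_mixture_lq(
    alpha = c(hi$alpha, lo$alpha),
    beta = c(hi$beta, lo$beta),
    omega = c(spec$omega_high, spec$omega_low)
  )
  list(
    alpha_c = mixed$alpha_c, beta_c = mixed$beta_c,
    alpha_hi = hi$alpha, alpha_lo = lo$alpha,
    beta_hi = hi$beta, beta_lo = lo$beta,
    z_hi = spec$high$zF_n, z_lo = spec$low$zF_n,
    z_c = combined_zF_n(c(spec$omega_high, spec$omega_low),
                        c(spec$high$zF_n, spec$low$zF_n))
  )
}

.require_schedule <- function(spec, simultaneous) {
  if (!inherits(spec, "mixture_spec")) {
    abort("`spec` must be a mixture_spec.")
  }
  is_sim <- startsWith(spec$schedule, "simultaneous")
  if (simultaneous && !is_sim) {
    abort("This operation requires a simultaneous schedule.")
  }
  if (!simultaneous && is_sim) {
    abort("This operation requires a sequential schedule.")
  }
  invisible(spec)
}

#' Simultaneous-mixture survival, independent action
#'
#' Each component keeps its own event statistics: the high-LET component
#' contributes no quadratic action until the dose exceeds its own per-track
#' specific energy `zF_n_hi`.  Three regimes in total dose `D`:
#' linear (`D <= zF_n_lo`), low-component quadratic only
#' (`zF_n_lo < D <= zF_n_hi`, quadratic weight `omega_lo^2 * beta_lo`), and
#' full mixed LQ (`D > zF_n_hi`, quadratic weight `beta_c`).  Connecting
#' constants are chosen so `ln S` is continuous at both thresholds.
#'
#' @param D Total dose in Gy (vectorised, `>= 0`).
#' @param spec A simultaneous [mixture_spec()].
#' @param cell A [cell_model()].
#' @return Surviving fraction, same length as `D`.
#' @export
survival_mixed_independent <- function(D, spec, cell) {
  .check_dose(D)
  .require_schedule(spec, simultaneous = TRUE)
  cf <- .mixture_coefficients(spec, cell)
  if (spec$omega_high == 0) {
    # no high-LET tracks at all: its threshold does not exist and the
    # exposure is the low component alone
    cf$z_hi <- cf$z_lo
  }
  b_mid <- spec$omega_low^2 * cf$beta_lo
  lnS_zlo <- -cf$alpha_c * cf$z_lo
  lnS_zhi <- lnS_zlo - cf$alpha_c * (cf$z_hi - cf$z_lo) -
    b_mid * (cf$z_hi - cf$z_lo)^2
  lnS <- ifelse(
    D <= cf$z_lo,
    -cf$alpha_c * D,
    ifelse(
      D <= cf$z_hi,
      lnS_zlo - cf$alpha_c * (D - cf$z_lo) - b_mid * (D - cf$z_lo)^2,
      lnS_zhi - cf$alpha_c * (D - cf$z_hi) - cf$beta_c * (D - cf$z_hi)^2
    )
  )
  exp(lnS)
}

#' Simultaneous-mixture survival, combined action
#'
#' The components pool their tracks: the number of tracks per unit dose is
#' the weighted sum of the components', so the effective per-track nucleus
#' specific energy is the harmonic mean `zF_n_c` ([combined_zF_n()]).  The
#' curve is linear up to `zF_n_c` and mixed LQ (`alpha_c`, `beta_c`)
#' beyond.  Because the low-LET component supplies many tracks per Gy,
#' `zF_n_c` is close to `zF_n_lo` (zero for an X-ray component) and the
#' quadratic action starts much earlier than under independence —
#' a synergistic prediction.
#'
#' @inheritParams survival_mixed_independent
#' @return Surviving fraction, same length as `D`.
#' @export
survival_mixed_combined <- function(D, spec, cell) {
  .check_dose(D)
  .require_schedule(spec, simultaneous = TRUE)
  cf <- .mixture_coefficients(spec, cell)
  lnS_zc <- -cf$alpha_c * cf$z_c
  lnS <- ifelse(
    D <= cf$z_c,
    -cf$alpha_c * D,
    lnS_zc - cf$alpha_c * (D - cf$z_c) - cf$beta_c * (D - cf$z_c)^2
  )
  exp(lnS)
}

#' Sensitised linear coefficient of a second radiation course
#'
#' Sublethal lesions left by a first course of dose `D1` (quadratic
#' coefficient `beta1`) pair with those of the second course, raising its
#' linear coefficient:
#' \deqn{\alpha_{2,seq} = \alpha_2 + 2\sqrt{\beta_1 \beta_2}\, D_1.}
#'
#' @param alpha2 Second-course linear coefficient, 1/Gy (`>= 0`).
#' @param beta1 First-course quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @param beta2 Second-course quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @param D1 First-course dose in Gy (`>= 0`).
#' @return The sensitised linear coefficient, `>= alpha2`.
#' @examples
#' sequential_alpha(0.10, 0.026, 0.026, 5)  # 0.36
#' @export
sequential_alpha <- function(alpha2, beta1, beta2, D1) {
  .assert_scalar_num(alpha2, "alpha2", lower = 0)
  .assert_scalar_num(beta1, "beta1", lower = 0)
  .assert_scalar_num(beta2, "beta2", lower = 0)
  .assert_scalar_num(D1, "D1", lower = 0)
  alpha2 + 2 * sqrt(beta1 * beta2) * D1
}

#' Sequential two-course survival curve
#'
#' Composes the survival of a first course of dose `D1` with a second
#' course whose linear coefficient is sensitised by [sequential_alpha()]
#' (no repair between courses).  Low-LET first: the first course seeds
#' enough tracks that the second (high-LET) course is Poisson from its
#' start — its linear-only regime is suppressed and it acts with its
#' saturated LQ coefficients (`(alpha0+beta0*zD)*fs`, `beta0`).  High-LET
#' first: the first course retains its linear opening segment, and the
#' second (low-LET) course is standard LQ with the sensitised alpha.
#'
#' @param D1 First-course dose in Gy (`>= 0`).
#' @param dose2_grid Second-course dose grid in Gy (`>= 0`).
#' @param spec A sequential [mixture_spec()] (its `first_course_dose` is
#'   ignored in favour of `D1`).
#' @param cell A [cell_model()].
#' @return A `survival_curve` tibble over total dose `D1 + D2`.
#' @export
survival_sequential <- function(D1, dose2_grid, spec, cell) {
  .assert_scalar_num(D1, "D1", lower = 0)
  .check_dose(dose2_grid)
  .require_schedule(spec, simultaneous = FALSE)
  low_first <- spec$schedule == "sequential_low_first"
  first_rad <- if (low_first) spec$low else spec$high
  second_rad <- if (low_first) spec$high else spec$low
  s_first <- survival_modified_mkm(D1, cell, first_rad)
  second <- component_lq(cell, second_rad)
  a2_seq <- sequential_alpha(second$alpha, cell$beta0, second$beta, D1)
  d2 <- sort(unique(dose2_grid))
  s <- s_first * exp(-(a2_seq * d2 + second$beta * d2^2))
  branch <- ifelse(d2 == 0, "first_course", "second_course")
  label <- sprintf("sequential:%s->%s", first_rad$label, second_rad$label)
  .new_survival_curve(D1 + d2, s, branch, label)
}

#' Compare the two simultaneous-mixture hypotheses on one dose grid
#'
#' Convenience wrapper evaluating both the independent- and combined-action
#' curves for the same radiation pair and weights, returned row-bound so
#' they chain directly into [plot_survival_curves()].
#'
#' @param high,low [radiation_quality()] objects (`low$zF_n <= high$zF_n`).
#' @param omega_high High-LET dose fraction (low gets `1 - omega_high`).
#' @param cell A [cell_model()].
#' @param dose Total-dose grid in Gy.
#' @return A `survival_curve` tibble with both hypotheses stacked and a
#'   `hypothesis` column.
#' @export
compare_mixture_hypotheses <- function(high, low, omega_high, cell, dose) {
  specs <- list(
    independent = mixture_spec(high, low, omega_high,
                               schedule = "simultaneous_independent"),
    combined = mixture_spec(high, low, omega_high,
                            schedule = "simultaneous_combined")
  )
  curves <- purrr::imap(specs, function(spec, name) {
    dplyr::mutate(survival_curve_mixed(spec, cell, dose), hypothesis = name)
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("survival_curve", class(tibble()))
  out
}

#' Tabulate a simultaneous-mixture survival curve
#'
#' Evaluates [survival_mixed_independent()] or [survival_mixed_combined()]
#' (according to the spec's schedule) on a dose grid, inserting the regime
#' thresholds as explicit rows and labelling each row with its regime.
#'
#' @param spec A simultaneous [mixture_spec()].
#' @param cell A [cell_model()].
#' @param dose Total-dose grid in Gy (`>= 0`).
#' @return A `survival_curve` tibble.
#' @export
survival_curve_mixed <- function(spec, cell, dose) {
  .check_dose(dose)
  .require_schedule(spec, simultaneous = TRUE)
  cf <- .mixture_coefficients(spec, cell)
  label <- sprintf("%s:%s+%s", spec$schedule,
                   spec$high$label, spec$low$label)
  if (spec$schedule == "simultaneous_independent") {
    dose <- .augment_grid(dose, c(cf$z_lo, cf$z_hi))
    s <- survival_mixed_independent(dose, spec, cell)
    branch <- ifelse(dose <= cf$z_lo & cf$z_lo > 0, "linear",
                     ifelse(dose <= cf$z_hi & cf$z_hi > 0,
                            "partial_quadratic", "full_quadratic"))
  } else {
    dose <- .augment_grid(dose, cf$z_c)
    s <- survival_mixed_combined(dose, spec, cell)
    branch <- ifelse(dose <= cf$z_c & cf$z_c > 0,
                     "linear", "linear_quadratic")
  }
  .new_survival_curve(dose, s, branch, label)
}
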