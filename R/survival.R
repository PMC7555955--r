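#' Overkill saturation factor
#'
#' At high event sizes, energy deposited beyond what is needed to kill a cell
#' is wasted ("overkill"), which saturates the effective linear coefficient.
#' The correction is
#' \deqn{f_s = \frac{1 - e^{-x}}{x}, \qquad
#'       x = (\alpha_0 + \beta_0 z_D)\, z_{D,n} + \beta_0 z_{D,n}^2,}
#' a number in `(0, 1]` that decreases monotonically with the dose-average
#' nucleus specific energy `zD_n`: `fs = 1` in the low-LET limit
#' (`zD_n = 0`) and `fs -> 1/x -> 0` for very large event sizes.  For
#' `x < 1e-6` the ratio is evaluated by its Taylor series
#' `1 - x/2 + x^2/6 - x^3/24` to avoid cancellation.
#'
#' @param alpha0 Intrinsic linear coefficient, 1/Gy (`>= 0`).
#' @param beta0 Intrinsic quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @param zD Domain dose-average specific energy per event, Gy (`>= 0`).
#' @param zD_n Nucleus dose-average specific energy per event, Gy (`>= 0`).
#' @return The saturation factor in `(0, 1]`.
#' @examples
#' saturation_factor(0.195, 0.026, 5.0, 1.0)  # ~0.8434
#' @export
saturation_factor <- function(alpha0, beta0, zD, zD_n) {
  .assert_scalar_num(alpha0, "alpha0", lower = 0)
  .assert_scalar_num(beta0, "beta0", lower = 0)
  .assert_scalar_num(zD, "zD", lower = 0)
  .assert_scalar_num(zD_n, "zD_n", lower = 0)
  x <- (alpha0 + beta0 * zD) * zD_n + beta0 * zD_n^2
  if (x < 1e-6) {
    1 - x / 2 + x^2 / 6 - x^3 / 24
  } else {
    -expm1(-x) / x
  }
}

.fs_for <- function(cell, rad) {
  saturation_factor(cell$alpha0, cell$beta0, rad$zD, rad$zD_n)
}

#' Mean lethal-lesion count per nucleus under the binomial track model
#'
#' Scaling the per-domain expectation to the nucleus and substituting the
#' track count `n = D / zF_n` gives a piecewise mean lesion count:
#' \deqn{\langle L_n \rangle = (\alpha_0 + \beta_0 z_D) D \quad (D \le z_{F,n})}
#' \deqn{\langle L_n \rangle = [\alpha_0 + \beta_0 (z_D - z_{F,n})] D +
#'       \beta_0 D^2 \quad (D > z_{F,n})}
#' continuous at the threshold.  Below `zF_n` at most one event per domain
#' is expected, so no pairwise (quadratic) lesion formation occurs.
#'
#' @param D Dose in Gy (vectorised, `>= 0`).
#' @param cell A [cell_model()].
#' @param rad A [radiation_quality()].
#' @return Mean lethal lesions per nucleus, same length as `D`.
#' @export
lethal_lesion_mean <- function(D, cell, rad) {
  .check_dose(D)
  z <- rad$zF_n
  ifelse(
    D <= z,
    (cell$alpha0 + cell$beta0 * rad$zD) * D,
    (cell$alpha0 + cell$beta0 * (rad$zD - z)) * D + cell$beta0 * D^2
  )
}

.check_dose <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0)) {
    abort("`D` must be finite and >= 0 (Gy).")
  }
  invisible(D)
}

#' Modified-MKM survival curve (linear opening segment)
#'
#' Surviving fraction for a single radiation under the low-dose modification
#' of the MKM: below the threshold `D = zF_n` (at most one event per
#' domain) the curve is purely exponential, and the quadratic term only
#' builds up beyond it:
#' \deqn{S(D) = \exp[-(\alpha_0+\beta_0 z_D) f_s D] \quad (D \le z_{F,n})}
#' \deqn{S(D) = S(z_{F,n}) \exp[-((\alpha_0+\beta_0(z_D - z_{F,n})) f_s
#'   (D - z_{F,n}) + \beta_0 (D - z_{F,n})^2)] \quad (D > z_{F,n})}
#' The saturation factor multiplies only the linear coefficient; the
#' quadratic `beta0` term is unsaturated.  For a low-LET field
#' (`zF_n = zD_n = zD = 0`) the threshold collapses and the curve is plain
#' linear-quadratic from the origin.
#'
#' @inheritParams lethal_lesion_mean
#' @return Surviving fraction in `(0, 1]`, same length as `D`.
#' @export
survival_modified_mkm <- function(D, cell, rad) {
  .check_dose(D)
  fs <- .fs_for(cell, rad)
  z <- rad$zF_n
  a_lin <- (cell$alpha0 + cell$beta0 * rad$zD) * fs
  lnS_thr <- -a_lin * z
  a_up <- (cell$alpha0 + cell$beta0 * (rad$zD - z)) * fs
  ifelse(
    D <= z,
    exp(-a_lin * D),
    exp(lnS_thr - (a_up * (D - z) + cell$beta0 * (D - z)^2))
  )
}

#' Original-MKM survival curve (linear-quadratic throughout)
#'
#' The Poisson-event formulation: linear-quadratic over the whole dose
#' range, with the same saturated linear coefficient,
#' `S(D) = exp[-(alpha0 + beta0*zD) fs D - beta0 D^2]`.
#' Differs from [survival_modified_mkm()] only by carrying the quadratic
#' term down to zero dose, so it lies at or below the modified curve
#' everywhere.
#'
#' @inheritParams lethal_lesion_mean
#' @return Surviving fraction in `(0, 1]`, same length as `D`.
#' @export
survival_original_mkm <- function(D, cell, rad) {
  .check_dose(D)
  fs <- .fs_for(cell, rad)
  exp(-((cell$alpha0 + cell$beta0 * rad$zD) * fs * D + cell$beta0 * D^2))
}

#' Plain linear-quadratic survival
#'
#' `S(D) = exp(-alpha*D - beta*D^2)`, the baseline photon dose-response.
#'
#' @param D Dose in Gy (vectorised, `>= 0`).
#' @param alpha Linear coefficient, 1/Gy (`>= 0`).
#' @param beta Quadratic coefficient, 1/Gy^2 (`>= 0`).
#' @return Surviving fraction in `(0, 1]`.
#' @examples
#' survival_lq(1, 0.195, 0.026)
#' @export
survival_lq <- function(D, alpha, beta) {
  .check_dose(D)
  .assert_scalar_num(alpha, "alpha", lower = 0)
  .assert_scalar_num(beta, "beta", lower = 0)
  exp(-(alpha * D + beta * D^2))
}

# Insert threshold doses into a grid (sorted, unique) so continuity across
# branch boundaries is representable and testable on the emitted curve.
.augment_grid <- function(dose, thresholds) {
  thr <- thresholds[thresholds > min(dose) & thresholds < max(dose)]
  sort(unique(c(dose, thr)))
}

.new_survival_curve <- function(dose, s, branch, model_label) {
  out <- tibble(
    dose = dose,
    surviving_fraction = s,
    branch = branch,
    model_label = model_label
  )
  class(out) <- c("survival_curve", class(out))
  out
}

#' Tabulate a single-radiation survival curve
#'
#' Evaluates one of the single-field models on a dose grid and returns a
#' tidy curve.  Threshold doses (e.g. `zF_n` for the modified MKM) are
#' inserted into the grid so the branch boundary is an explicit row, and
#' each row is labelled with the regime that produced it.
#'
#' @param cell A [cell_model()].
#' @param rad A [radiation_quality()].
#' @param dose Dose grid in Gy (`>= 0`); need not contain the threshold.
#' @param model `"modified_mkm"` (default), `"original_mkm"` or `"lq"`
#'   (plain LQ with the cell's `alpha0`, `beta0`).
#' @return A tibble of class `survival_curve` with columns `dose`,
#'   `surviving_fraction`, `branch`, `model_label`.
#' @examples
#' v79 <- cell_model(0.195, 0.026)
#' ar <- radiation_quality("Ar", 86, v79)
#' survival_curve(v79, ar, seq(0, 6, by = 0.5))
#' @export
survival_curve <- function(cell, rad, dose,
                           model = c("modified_mkm", "original_mkm", "lq")) {
  model <- match.arg(model)
  .check_dose(dose)
  if (length(dose) < 1) abort("`dose` must be non-empty.")
  dose <- if (model == "modified_mkm") {
    .augment_grid(dose, rad$zF_n)
  } else {
    sort(unique(dose))
  }
  label <- paste0(model, ":", rad$label)
  s <- switch(model,
    modified_mkm = survival_modified_mkm(dose, cell, rad),
    original_mkm = survival_original_mkm(dose, cell, rad),
    lq = survival_lq(dose, cell$alpha0, cell$beta0)
  )
  branch <- switch(model,
    modified_mkm = ifelse(dose <= rad$zF_n & rad$zF_n > 0,
                          "linear", "linear_quadratic"),
    original_mkm = rep("linear_quadratic", length(dose)),
    lq = rep("linear_quadratic", length(dose))
  )
  .new_survival_curve(dose, s, branch, label)
}

#' Write / read survival curves as CSV
#'
#' Plain-text exchange format: columns `dose_Gy`, `surviving_fraction`,
#' `branch`, `model_label`; `#` lines carry metadata and are skipped on
#' read.
#'
#' @param curve A `survival_curve` tibble.
#' @param path File path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `write_survival_curve()` returns `path` invisibly;
#'   `read_survival_curve()` returns a `survival_curve` tibble.
#' @export
write_survival_curve <- function(curve, path, comments = character()) {
  stopifnot(is.data.frame(curve))
  out <- tibble(
    dose_Gy = curve$dose,
    surviving_fraction = curve$surviving_fraction,
    branch = curve$branch,
    model_label = curve$model_label
  )
  if (length(comments) > 0) {
    readr::write_lines(paste0("# ", comments), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_survival_curve
#' @export
read_survival_curve <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("dose_Gy", "surviving_fraction", "branch", "model_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  .new_survival_curve(df$dose_Gy, df$surviving_fraction,
                      as.character(df$branch), as.character(df$model_label))
}

#' Plot survival curves
#'
#' Semi-log plot (log10 surviving fraction against dose) of one or more
#' curves, coloured by model label.
#'
#' @param curves A `survival_curve` tibble, or several row-bound together.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(curves, ...) {
  stopifnot(is.data.frame(curves))
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$dose, y = .data$surviving_fraction,
                 colour = .data$model_label)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival_curves
#' @param object A `survival_curve` tibble.
#' @export
autoplot.survival_curve <- function(object, ...) {
  plot_survival_curves(object, ...)
}
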