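#' Fit the linear-quadratic model to survival data
#'
#' Linearises the LQ model by fitting `-ln S = alpha*D + beta*D^2` through
#' the origin by least squares, the standard treatment of clonogenic
#' survival points.  Both coefficients are rate constants and are
#' constrained non-negative by projection: a negative estimate is clipped
#' to zero and the other coefficient refitted.  Parameter standard
#' deviations come from the fit covariance; the coefficient of
#' determination is computed on the `ln S` scale.
#'
#' @param data A data frame with columns `dose` (Gy) and
#'   `surviving_fraction` (`> 0`), optionally `sd` (per-point standard
#'   deviation of `surviving_fraction`); at least 3 distinct doses.
#' @param weighting `"none"` (default, unweighted) or
#'   `"inverse_variance"` (weights `1/sd_lnS^2` with
#'   `sd_lnS = sd / surviving_fraction`; requires an `sd` column).
#' @return An object of class `lq_fit` with fields `alpha`, `beta`,
#'   `alpha_sd`, `beta_sd`, `r_squared`, `n` and the underlying data.
#'   Supports [generics::tidy()], [generics::glance()], `print()` and
#'   `autoplot()`.
#' @examples
#' d <- tibble::tibble(dose = 0:6,
#'                     surviving_fraction = survival_lq(0:6, 0.195, 0.026))
#' fit_lq(d)
#' @export
fit_lq <- function(data, weighting = c("none", "inverse_variance")) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(data) ||
      !all(c("dose", "surviving_fraction") %in% names(data))) {
    abort("`data` needs `dose` and `surviving_fraction` columns.")
  }
  d <- data$dose
  s <- data$surviving_fraction
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("Doses must be finite and >= 0.")
  }
  bad <- which(!is.finite(s) | s <= 0)
  if (length(bad) > 0) {
    abort(paste0("Surviving fractions must be > 0; offending row(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (length(unique(d)) < 3) {
    abort("At least 3 distinct doses are required for an LQ fit.")
  }
  w <- NULL
  if (weighting == "inverse_variance") {
    if (!"sd" %in% names(data) || any(!is.finite(data$sd)) ||
        any(data$sd <= 0)) {
      abort("`inverse_variance` weighting needs a positive `sd` column.")
    }
    w <- (s / data$sd)^2  # delta method: sd_lnS = sd/S
  }

  y <- -log(s)
  df <- data.frame(y = y, d1 = d, d2 = d^2)
  fit2 <- function(formula) {
    if (is.null(w)) lm(formula, data = df) else lm(formula, data = df, weights = w)
  }
  full <- fit2(y ~ 0 + d1 + d2)
  alpha <- unname(coef(full)["d1"])
  beta <- unname(coef(full)["d2"])
  # vcov warns on an interpolating fit; the zero residual itself is fine
  ses <- suppressWarnings(sqrt(diag(vcov(full))))
  alpha_sd <- unname(ses["d1"])
  beta_sd <- unname(ses["d2"])
  if (beta < 0) {
    lin <- fit2(y ~ 0 + d1)
    alpha <- max(unname(coef(lin)["d1"]), 0)
    alpha_sd <- suppressWarnings(sqrt(diag(vcov(lin))))[["d1"]]
    beta <- 0
    beta_sd <- NA_real_
    model <- lin
  } else if (alpha < 0) {
    quad <- fit2(y ~ 0 + d2)
    beta <- max(unname(coef(quad)["d2"]), 0)
    beta_sd <- suppressWarnings(sqrt(diag(vcov(quad))))[["d2"]]
    alpha <- 0
    alpha_sd <- NA_real_
    model <- quad
  } else {
    model <- full
  }

  yhat <- alpha * d + beta * d^2
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, -Inf) else 1 - ss_res / ss_tot

  structure(
    list(alpha = alpha, beta = beta,
         alpha_sd = alpha_sd, beta_sd = beta_sd,
         r_squared = r2, n = length(d),
         weighting = weighting, model = model, data = as_tibble(data)),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("<lq_fit>\n")
  cat(sprintf("  alpha = %.4g +/- %.2g  /Gy\n", x$alpha, x$alpha_sd))
  cat(sprintf("  beta  = %.4g +/- %.2g  /Gy^2\n", x$beta, x$beta_sd))
  cat(sprintf("  R^2 (on ln S) = %.4g,  n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_lq
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @export
tidy.lq_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$alpha_sd, x$beta_sd)
  )
}

#' @rdname fit_lq
#' @export
glance.lq_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n, weighting = x$weighting)
}

#' @rdname fit_lq
#' @param object An `lq_fit` object.
#' @export
autoplot.lq_fit <- function(object, ...) {
  grid <- seq(0, max(object$data$dose), length.out = 101)
  curve <- tibble(dose = grid,
                  surviving_fraction = survival_lq(grid, object$alpha,
                                                   object$beta))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dose,
                               y = .data$surviving_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction") +
    ggplot2::theme_minimal()
}

#' Coefficient of determination of a model against survival data
#'
#' `R^2 = 1 - SS_res/SS_tot` computed on `ln S` (the scale on which the LQ
#' model is linear).  The model may be a function `D -> S`, a
#' `survival_curve` tibble (log-linearly interpolated between grid points;
#' every data dose must fall inside the curve's range), or an `lq_fit`.
#'
#' @param model A function of dose returning surviving fraction, a
#'   `survival_curve` tibble, or an `lq_fit`.
#' @param data A data frame with `dose` and `surviving_fraction` columns
#'   (at least 2 points, `surviving_fraction > 0`).
#' @return The coefficient of determination (`<= 1`, possibly negative).
#' @export
r_squared <- function(model, data) {
  if (!is.data.frame(data) ||
      !all(c("dose", "surviving_fraction") %in% names(data))) {
    abort("`data` needs `dose` and `surviving_fraction` columns.")
  }
  if (nrow(data) < 2) {
    abort("At least 2 data points are required.")
  }
  if (any(data$surviving_fraction <= 0)) {
    abort("Surviving fractions must be > 0.")
  }
  y <- log(data$surviving_fraction)
  yhat <- .model_lnS(model, data$dose)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(ifelse(ss_res == 0, 1, -Inf))
  }
  1 - ss_res / ss_tot
}

.model_lnS <- function(model, dose) {
  if (inherits(model, "lq_fit")) {
    return(-(model$alpha * dose + model$beta * dose^2))
  }
  if (is.function(model)) {
    return(log(model(dose)))
  }
  if (is.data.frame(model) &&
      all(c("dose", "surviving_fraction") %in% names(model))) {
    if (any(dose < min(model$dose)) || any(dose > max(model$dose))) {
      abort("Model curve does not cover all data doses.")
    }
    return(approx(model$dose, log(model$surviving_fraction),
                  xout = dose, ties = "ordered")$y)
  }
  abort("`model` must be a function, a survival_curve or an lq_fit.")
}
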