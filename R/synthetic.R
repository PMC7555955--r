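#' Generate a synthetic survival dataset with known ground truth
#'
#' Evaluates a survival model on a dose grid and optionally perturbs it
#' with multiplicative lognormal noise, `S_obs = S * exp(e)`,
#' `e ~ Normal(0, sigma_lnS^2)`, independently per point and replicate.
#' Lognormal noise keeps survival positive and is additive on the `ln S`
#' scale the fit operates on; observed values may exceed 1, as real
#' clonogenic scatter does, and are not clipped.
#'
#' @param model A function `D -> S`, a `survival_curve` tibble, or an
#'   `lq_fit`.
#' @param dose Dose grid in Gy (`>= 0`).
#' @param noise `"none"` or `"lognormal"`.
#' @param sigma_lnS Noise standard deviation on `ln S` (`>= 0`; default
#'   0.1, typical clonogenic-assay scatter).
#' @param replicates Replicates per dose (integer `>= 1`).
#' @param seed Integer seed; required when `noise != "none"`.  The same
#'   seed reproduces the dataset exactly.
#' @param label Dataset label.
#' @return A tibble with columns `dose`, `surviving_fraction`,
#'   `replicate`, `label`.
#' @examples
#' generate_survival_dataset(function(D) survival_lq(D, 0.195, 0.026),
#'                           dose = 0:6, noise = "lognormal",
#'                           sigma_lnS = 0.1, seed = 7)
#' @export
generate_survival_dataset <- function(model, dose,
                                      noise = c("none", "lognormal"),
                                      sigma_lnS = 0.1, replicates = 1,
                                      seed = NULL, label = "synthetic") {
  noise <- match.arg(noise)
  .check_dose(dose)
  .assert_scalar_num(sigma_lnS, "sigma_lnS", lower = 0)
  .assert_scalar_num(replicates, "replicates", lower = 1)
  if (replicates != floor(replicates)) abort("`replicates` must be an integer.")
  if (noise != "none" && is.null(seed)) {
    abort("`seed` is required when noise is not \"none\".")
  }
  lnS <- .model_lnS(model, dose)
  out <- tidyr::expand_grid(replicate = seq_len(replicates),
                            tibble(dose = dose, lnS = lnS))
  eps <- if (noise == "none") {
    0
  } else {
    withr::with_seed(as.integer(seed),
                     rnorm(nrow(out), mean = 0, sd = sigma_lnS))
  }
  tibble(
    dose = out$dose,
    surviving_fraction = exp(out$lnS + eps),
    replicate = as.integer(out$replicate),
    label = label
  )
}

#' Built-in table of analysed mixed-field experiments
#'
#' Parameter records for the four published V79 mixed-irradiation
#' experiments the model was evaluated against: ion LET and the derived
#' per-track nucleus specific energy `zF_n`, the delivery schedule, the
#' photon LQ fit (`alpha_x`, `beta_x` with standard deviations), the
#' domain radius `rd` derived from `(alpha/beta)_x`, and the nucleus
#' radius `rn` (3.0 um except the Fe-56 experiment, refit at 4.5 um
#' because its very high LET makes the fixed-nucleus approximation break
#' down).
#'
#' @return A tibble with one row per experiment.
#' @examples
#' table1_records()
#' @export
table1_records <- function() {
  tibble(
    publication = c("Furusawa, 2002", "Furusawa, 2002",
                    "Ngo, 1981", "McNally, 1988"),
    radiation = c("Ar", "Fe-56", "Ne-10", "alpha"),
    let_keV_um = c(86, 442, 183, 140),
    zF_n_Gy = c(0.49, 1.11, 1.04, 0.80),
    schedule = c("simultaneous", "simultaneous",
                 "simultaneous+sequential_low_first",
                 "sequential_high_first"),
    alpha_x = c(0.195, 0.18, 0.10, 0.23),
    alpha_x_sd = c(0.016, 0.03, 0.03, 0.03),
    beta_x = c(0.0260, 0.016, 0.026, 0.025),
    beta_x_sd = c(0.0018, 0.004, 0.006, 0.003),
    rd_um = c(0.295, 0.256, 0.371, 0.279),
    rn_um = c(3.0, 4.5, 3.0, 3.0)
  )
}

#' Write / read survival datasets as CSV
#'
#' Columns `dose_Gy`, `surviving_fraction`, optional `sd`, `replicate`,
#' `label`; `#` lines carry metadata and are skipped on read.
#'
#' @param data A survival dataset tibble (`dose`, `surviving_fraction`,
#'   optionally `sd`, `replicate`, `label`).
#' @param path File path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `write_survival_dataset()` returns `path` invisibly;
#'   `read_survival_dataset()` returns a tibble with `dose` and
#'   `surviving_fraction` columns (plus any optional ones present).
#' @export
write_survival_dataset <- function(data, path, comments = character()) {
  stopifnot(is.data.frame(data))
  out <- tibble(dose_Gy = data$dose,
                surviving_fraction = data$surviving_fraction)
  for (col in c("sd", "replicate", "label")) {
    if (col %in% names(data)) out[[col]] <- data[[col]]
  }
  if (length(comments) > 0) {
    readr::write_lines(paste0("# ", comments), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_survival_dataset
#' @export
read_survival_dataset <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("dose_Gy", "surviving_fraction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(dose = df$dose_Gy,
                surviving_fraction = df$surviving_fraction)
  for (col in c("sd", "replicate", "label")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  out
}
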