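test_that("mixed-field LQ coefficients follow the dual-action forms", {
  # weight 1 on one component returns it exactly
  one <- tdra_mixture_lq(c(0.7, 0.2), c(0.03, 0.02), c(1, 0))
  expect_equal(one$alpha_c, 0.7)
  expect_equal(one$beta_c, 0.03)
  # equal betas are invariant under any weights
  eq <- tdra_mixture_lq(c(0.5, 0.1), c(0.026, 0.026), c(0.3, 0.7))
  expect_equal(eq$beta_c, 0.026)
  # derived oracle: direct arithmetic on the square-root form
  mix <- tdra_mixture_lq(c(0.1, 0.2), c(0.016, 0.026), c(0.5, 0.5))
  expect_equal(mix$beta_c, (0.5 * sqrt(0.016) + 0.5 * sqrt(0.026))^2)
  expect_equal(round(mix$beta_c, 5), 0.02070)
  expect_equal(mix$alpha_c, 0.15)
  # three-component form reduces to nested two-component mixing
  w3 <- c(0.2, 0.3, 0.5)
  a3 <- c(0.6, 0.3, 0.15)
  b3 <- c(0.03, 0.02, 0.026)
  m3 <- tdra_mixture_lq(a3, b3, w3)
  inner <- tdra_mixture_lq(a3[1:2], b3[1:2], c(0.2, 0.3) / 0.5)
  outer <- tdra_mixture_lq(c(inner$alpha_c, a3[3]),
                           c(inner$beta_c, b3[3]), c(0.5, 0.5))
  expect_equal(m3$alpha_c, outer$alpha_c, tolerance = 1e-12)
  expect_equal(m3$beta_c, outer$beta_c, tolerance = 1e-12)
  expect_error(tdra_mixture_lq(c(0.1, 0.2), c(-0.01, 0.02), c(0.5, 0.5)),
               "beta")
  expect_error(tdra_mixture_lq(c(0.1, 0.2), c(0.01, 0.02), c(0.5, 0.6)),
               "sum to 1")
})

test_that("mixture_spec validates ordering, weights and schedules", {
  cell <- v79_ar_cell()
  ar <- ar_quality(cell)
  xr <- xray_quality()
  expect_error(mixture_spec(xr, ar, 0.5), "ordering")
  expect_error(mixture_spec(ar, xr, 0.5, 0.6), "equal 1")
  expect_error(mixture_spec(ar, xr, schedule = "sequential_low_first"),
               "first_course_dose")
  spec <- mixture_spec(ar, xr, 0.5, schedule = "simultaneous_independent")
  expect_error(survival_sequential(1, 0:3, spec, cell), "sequential")
  seq_spec <- mixture_spec(ar, xr, schedule = "sequential_low_first",
                           first_course_dose = 5)
  expect_error(survival_mixed_independent(1, seq_spec, cell), "simultaneous")
})

test_that("independent-action mixture is continuous at both thresholds", {
  withr::with_seed(31, {
    for (i in 1:10) {
      case <- random_mix_case()
      spec <- mixture_spec(case$high, case$low, case$omega_high,
                           schedule = "simultaneous_independent")
      f <- function(D) survival_mixed_independent(D, spec, case$cell)
      expect_identical(f(0), 1)
      expect_lt(lnS_jump(f, case$low$zF_n), 1e-9)
      expect_lt(lnS_jump(f, case$high$zF_n), 1e-9)
      D <- seq(0, 12, length.out = 120)
      expect_true(all(diff(f(D)) <= 1e-14))
    }
  })
})

test_that("pure X-ray degenerate mixture is plain LQ at all doses", {
  cell <- v79_ar_cell()
  ar <- ar_quality(cell)
  xr <- xray_quality()
  spec <- mixture_spec(ar, xr, omega_high = 0,
                       schedule = "simultaneous_independent")
  D <- seq(0, 10, by = 0.25)
  expect_equal(survival_mixed_independent(D, spec, cell),
               survival_lq(D, cell$alpha0, cell$beta0), tolerance = 1e-12)
  spec_c <- mixture_spec(ar, xr, omega_high = 0,
                         schedule = "simultaneous_combined")
  expect_equal(survival_mixed_combined(D, spec_c, cell),
               survival_lq(D, cell$alpha0, cell$beta0), tolerance = 1e-12)
})

test_that("combined-action threshold is the harmonic mean and curve continuous", {
  cell <- v79_ar_cell()
  # equal thresholds: single threshold at the common value
  r1 <- radiation_quality("a", 86, cell)
  r2 <- radiation_quality("b", 86, cell)
  spec_eq <- mixture_spec(r1, r2, 0.4, schedule = "simultaneous_combined")
  zc <- combined_zF_n(c(0.4, 0.6), c(r1$zF_n, r2$zF_n))
  expect_equal(zc, r1$zF_n)
  f <- function(D) survival_mixed_combined(D, spec_eq, cell)
  expect_lt(lnS_jump(f, zc), 1e-9)
  # balanced weights, very unequal thresholds: z_c hugs the low value
  hi <- radiation_quality("hi", 200, cell)
  lo <- radiation_quality("lo", 2, cell)
  zc2 <- combined_zF_n(c(0.5, 0.5), c(hi$zF_n, lo$zF_n))
  expect_lt(zc2, 2.2 * lo$zF_n)  # within the omega-scaled correction
  expect_gte(zc2, lo$zF_n)
})

test_that("combined action predicts lower survival than independent action", {
  withr::with_seed(41, {
    for (i in 1:12) {
      case <- random_mix_case()
      spec_i <- mixture_spec(case$high, case$low, case$omega_high,
                             schedule = "simultaneous_independent")
      spec_c <- mixture_spec(case$high, case$low, case$omega_high,
                             schedule = "simultaneous_combined")
      D <- seq(0, 12, length.out = 150)
      s_i <- survival_mixed_independent(D, spec_i, case$cell)
      s_c <- survival_mixed_combined(D, spec_c, case$cell)
      expect_true(all(s_c <= s_i + 1e-14))
    }
  })
})

test_that("mixtures converge to single-field curves as a weight vanishes", {
  cell <- v79_ar_cell()
  ar <- ar_quality(cell)
  xr <- xray_quality()
  D <- seq(0, 8, length.out = 100)
  lq <- survival_lq(D, cell$alpha0, cell$beta0)
  fmix <- function(w, schedule) {
    spec <- mixture_spec(ar, xr, omega_high = w, schedule = schedule)
    if (schedule == "simultaneous_independent") {
      survival_mixed_independent(D, spec, cell)
    } else {
      survival_mixed_combined(D, spec, cell)
    }
  }
  # omega_high -> 0, combined action: the X-ray LQ curve at all doses
  # (the combined threshold is 0 whenever an X-ray component is present)
  gaps0c <- vapply(c(1e-2, 1e-4, 1e-6),
                   function(w) max(abs(fmix(w, "simultaneous_combined") - lq)),
                   numeric(1))
  expect_true(all(diff(gaps0c) < 0))
  expect_lt(gaps0c[3], 1e-4)
  # omega_high = 0 exactly, independent action: the low-only curve at all
  # doses (the absent component's threshold does not apply)
  expect_equal(fmix(0, "simultaneous_independent"), lq, tolerance = 1e-12)
  # omega_high -> 0+, independent action: convergence on [0, zF_n_hi]; the
  # printed piecewise form re-zeroes the quadratic at zF_n_hi, leaving a
  # known ln S offset 2*beta*z*(D - z) beyond it even in the limit
  onlin <- D <= ar$zF_n
  gaps0i <- vapply(c(1e-2, 1e-4, 1e-6), function(w) {
    max(abs(fmix(w, "simultaneous_independent")[onlin] - lq[onlin]))
  }, numeric(1))
  expect_true(all(diff(gaps0i) < 0))
  expect_lt(gaps0i[3], 1e-4)
  z <- ar$zF_n
  beyond <- D > z
  lim_lnS_gap <- log(fmix(1e-8, "simultaneous_independent")[beyond]) -
    log(lq[beyond])
  expect_equal(lim_lnS_gap, 2 * cell$beta0 * z * (D[beyond] - z),
               tolerance = 1e-4)
  # omega_high -> 1, independent action: the high-LET curve on the shared
  # linear regime [0, zF_n_hi]
  ref <- survival_modified_mkm(D[onlin], cell, ar)
  gaps1i <- vapply(c(1e-2, 1e-4, 1e-6), function(w) {
    max(abs(fmix(1 - w, "simultaneous_independent")[onlin] - ref))
  }, numeric(1))
  expect_true(all(diff(gaps1i) < 0))
  expect_lt(gaps1i[3], 1e-5)
  # omega_high -> 1, combined action: any X-ray admixture keeps the
  # combined threshold at 0, so the limit is the original (Poisson) MKM
  # curve of the high-LET field
  orig <- survival_original_mkm(D, cell, ar)
  gaps1c <- vapply(c(1e-2, 1e-4, 1e-6), function(w) {
    max(abs(fmix(1 - w, "simultaneous_combined") - orig))
  }, numeric(1))
  expect_true(all(diff(gaps1c) < 0))
  expect_lt(gaps1c[3], 1e-4)
})

test_that("sequential alpha is sensitised by the first course", {
  expect_equal(sequential_alpha(0.10, 0.026, 0.026, 0), 0.10)
  expect_equal(sequential_alpha(0.10, 0, 0.026, 5), 0.10)
  # equal-beta case: alpha2 + 2*beta*D1
  expect_equal(sequential_alpha(0.10, 0.026, 0.026, 5), 0.36)
  # monotone non-decreasing in D1, beta1, beta2
  expect_true(all(diff(vapply(0:5, function(d) {
    sequential_alpha(0.1, 0.02, 0.03, d)
  }, numeric(1))) >= 0))
  expect_gt(sequential_alpha(0.1, 0.03, 0.03, 2),
            sequential_alpha(0.1, 0.02, 0.03, 2))
})

test_that("sequential curves compose first-course survival with sensitised LQ", {
  cell <- v79_ar_cell()
  ar <- ar_quality(cell)
  xr <- xray_quality()
  # D2 = 0: the curve is the first-course survival at total dose D1
  spec_lf <- mixture_spec(ar, xr, schedule = "sequential_low_first",
                          first_course_dose = 5)
  at_d1 <- survival_sequential(5, 0, spec_lf, cell)
  expect_equal(at_d1$dose, 5)
  expect_equal(at_d1$surviving_fraction,
               survival_lq(5, cell$alpha0, cell$beta0))
  # low-first with a zero-threshold second course: plain LQ continuation
  xr2 <- xray_quality("X2")
  spec_xx <- mixture_spec(xr2, xr, schedule = "sequential_low_first",
                          first_course_dose = 3)
  d2 <- seq(0, 4, by = 0.5)
  got <- survival_sequential(3, d2, spec_xx, cell)
  a2_seq <- sequential_alpha(cell$alpha0, cell$beta0, cell$beta0, 3)
  manual <- survival_lq(3, cell$alpha0, cell$beta0) *
    exp(-(a2_seq * d2 + cell$beta0 * d2^2))
  expect_equal(got$surviving_fraction, manual)
  # high-first composition oracle: 0.5 Gy of alpha particles then X-rays
  mcnally <- cell_model(0.226, 0.025)
  alpha_rad <- radiation_quality("alpha", 140, mcnally)
  spec_hf <- mixture_spec(alpha_rad, xr, schedule = "sequential_high_first",
                          first_course_dose = 0.5)
  d2 <- seq(0, 6, by = 1)
  got_hf <- survival_sequential(0.5, d2, spec_hf, mcnally)
  a2_seq_hf <- mcnally$alpha0 + 2 * mcnally$beta0 * 0.5
  manual_hf <- survival_modified_mkm(0.5, mcnally, alpha_rad) *
    exp(-(a2_seq_hf * d2 + mcnally$beta0 * d2^2))
  expect_equal(got_hf$surviving_fraction, manual_hf)
  expect_equal(got_hf$dose, 0.5 + d2)
  expect_true(all(diff(got_hf$surviving_fraction) <= 0))
})

test_that("mixture curve tables carry thresholds, branches and hypotheses", {
  cell <- v79_ar_cell()
  ar <- ar_quality(cell)
  xr <- xray_quality()
  spec <- mixture_spec(ar, xr, 0.5, schedule = "simultaneous_independent")
  curve <- survival_curve_mixed(spec, cell, seq(0, 6, by = 0.5))
  expect_true(ar$zF_n %in% curve$dose)
  expect_true(all(c("partial_quadratic", "full_quadratic") %in% curve$branch))
  both <- compare_mixture_hypotheses(ar, xr, 0.5, cell, seq(0, 6, by = 0.5))
  expect_setequal(unique(both$hypothesis), c("independent", "combined"))
  wide <- tidyr::pivot_wider(both[, c("dose", "surviving_fraction", "hypothesis")],
                             names_from = "hypothesis",
                             values_from = "surviving_fraction")
  ok <- !is.na(wide$combined) & !is.na(wide$independent)
  expect_true(all(wide$combined[ok] <= wide$independent[ok] + 1e-14))
})
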