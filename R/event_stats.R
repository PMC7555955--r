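#' Per-domain event-count distribution under the binomial track model
#'
#' Each of `n` tracks crossing the nucleus interacts with a given domain
#' independently with probability `p`, so the number of events in the domain
#' is Binomial(`n`, `p`).  At `n = 1` this degenerates to a Bernoulli trial:
#' no domain can see more than one event, which is the regime behind the
#' purely linear low-dose survival segment.
#'
#' @param n Number of tracks crossing the nucleus (integer `>= 0`); the
#'   maximum number of events a domain can receive.
#' @param p Per-track probability of interacting with the domain, in
#'   `[0, 1]`.
#' @return A tibble with columns `events` (0..n) and `probability`, carrying
#'   `n` and `p` as attributes; class `event_distribution`.
#' @examples
#' event_count_distribution(4, 0.2)
#' @export
event_count_distribution <- function(n, p) {
  .assert_scalar_num(n, "n", lower = 0)
  if (n != floor(n)) abort("`n` must be an integer.")
  .assert_scalar_num(p, "p", lower = 0, upper = 1)
  out <- tibble(
    events = 0:n,
    probability = dbinom(0:n, size = n, prob = p)
  )
  attr(out, "n") <- as.integer(n)
  attr(out, "p") <- p
  class(out) <- c("event_distribution", class(out))
  out
}

#' Dispersion quotient of an event-count distribution
#'
#' Computes by direct summation the quotient
#' \deqn{\frac{\sum_i (i^2 - i)\,\phi_i}{\left(\sum_i i\,\phi_i\right)^2}}
#' which weights the quadratic (pairwise-interaction) term of the mean
#' lethal-lesion count.  For a Binomial(n, p) distribution it equals
#' `1 - 1/n` for every `p`, independent of the interaction probability; the
#' Poisson limit is 1, and at `n = 1` it vanishes — no quadratic action.
#'
#' @param dist An [event_count_distribution()] result, or any data frame
#'   with `events` and `probability` columns.
#' @return The dimensionless quotient.
#' @export
dispersion_quotient <- function(dist) {
  if (!is.data.frame(dist) ||
      !all(c("events", "probability") %in% names(dist))) {
    abort("`dist` must have `events` and `probability` columns.")
  }
  i <- dist$events
  phi <- dist$probability
  m1 <- sum(i * phi)
  if (m1 <= 0) {
    abort("`dist` has zero mean: the dispersion quotient is undefined.")
  }
  sum((i^2 - i) * phi) / m1^2
}

#' Single-event specific-energy spectrum (two-moment summary)
#'
#' The model needs only the first two moments of the per-event specific
#' energy deposited in a domain: the frequency mean `zF` and the variance
#' `Vz1`.  The dose-mean per event follows as `zD = zF + Vz1/zF`.
#'
#' @param zF Frequency-mean specific energy per event, Gy (`> 0`).
#' @param Vz1 Variance of the single-event specific energy, Gy^2 (`>= 0`).
#' @return An object of class `single_event_spectrum` with fields `zF`,
#'   `Vz1` and derived `zD`.
#' @export
single_event_spectrum <- function(zF, Vz1) {
  .assert_scalar_num(zF, "zF", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(Vz1, "Vz1", lower = 0)
  structure(
    list(zF = zF, Vz1 = Vz1, zD = zF + Vz1 / zF),
    class = "single_event_spectrum"
  )
}

# Draw per-domain total specific energy: sum of `counts[j]` iid single-event
# energies with mean zF, variance Vz1.  Gamma sampling exploits closure under
# summation (sum of k Gamma(s, theta) is Gamma(k s, theta)); lognormal sums
# have no closed form and are accumulated per event.
.sample_domain_z <- function(counts, spectrum, event_dist) {
  zF <- spectrum$zF
  Vz1 <- spectrum$Vz1
  if (Vz1 == 0) {
    return(counts * zF)
  }
  if (event_dist == "gamma") {
    shape <- zF^2 / Vz1
    scale <- Vz1 / zF
    z <- numeric(length(counts))
    hit <- counts > 0
    z[hit] <- rgamma(sum(hit), shape = shape * counts[hit], scale = scale)
    z
  } else {
    sdlog2 <- log(1 + Vz1 / zF^2)
    mulog <- log(zF) - sdlog2 / 2
    z <- numeric(length(counts))
    idx <- rep.int(seq_along(counts), counts)
    if (length(idx) > 0) {
      draws <- rlnorm(length(idx), meanlog = mulog, sdlog = sqrt(sdlog2))
      sums <- rowsum(draws, group = idx)
      z[as.integer(rownames(sums))] <- sums[, 1]
    }
    z
  }
}

#' Monte-Carlo estimate of the mean lethal-lesion count per domain
#'
#' Brute-force simulator of the binomial track model: for each of
#' `n_domains` domains, draw an event count from Binomial(`n`, `p`), draw
#' the total specific energy `z` as the sum of that many independent
#' single-event energies (mean `zF`, variance `Vz1`), and score
#' `a*z + b*z^2` lethal lesions.  Serves as the independent oracle for the
#' closed forms: the expectation is
#' `(a + b*zD)*D + b*(1 - 1/n)*D^2` with per-domain dose `D = n*p*zF` and
#' `zD = zF + Vz1/zF`; at `n = 1` the quadratic term vanishes.
#'
#' @param n Number of tracks (integer `>= 0`).
#' @param p Per-track interaction probability in `[0, 1]`.
#' @param spectrum A [single_event_spectrum()].
#' @param a Linear lesion coefficient per domain, lesions/Gy (`>= 0`).
#' @param b Quadratic lesion coefficient per domain, lesions/Gy^2 (`>= 0`).
#' @param n_domains Number of simulated domains (integer `>= 1`).
#' @param seed Integer seed; the same seed reproduces the estimate exactly.
#' @param event_dist Per-event sampling distribution matching the two
#'   moments: `"gamma"` (default) or `"lognormal"`.  Only the moments enter
#'   the analytics, so the choice is a positivity-preserving convention.
#' @return A one-row tibble: `mean_lethal_lesions`, `se`, `n_domains`.
#' @export
simulate_domain_lethality <- function(n, p, spectrum, a, b, n_domains,
                                      seed,
                                      event_dist = c("gamma", "lognormal")) {
  .assert_scalar_num(n, "n", lower = 0)
  if (n != floor(n)) abort("`n` must be an integer.")
  .assert_scalar_num(p, "p", lower = 0, upper = 1)
  if (!inherits(spectrum, "single_event_spectrum")) {
    abort("`spectrum` must be a single_event_spectrum.")
  }
  .assert_scalar_num(a, "a", lower = 0)
  .assert_scalar_num(b, "b", lower = 0)
  .assert_scalar_num(n_domains, "n_domains", lower = 1)
  if (n_domains != floor(n_domains)) abort("`n_domains` must be an integer.")
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  .assert_scalar_num(seed, "seed")
  event_dist <- match.arg(event_dist)

  lesions <- withr::with_seed(as.integer(seed), {
    counts <- rbinom(n_domains, size = n, prob = p)
    z <- .sample_domain_z(counts, spectrum, event_dist)
    a * z + b * z^2
  })
  tibble(
    mean_lethal_lesions = mean(lesions),
    se = sd(lesions) / sqrt(n_domains),
    n_domains = as.integer(n_domains)
  )
}

#' Closed-form mean lethal-lesion count per domain
#'
#' Analytic expectation matching [simulate_domain_lethality()]:
#' `(a + b*zD)*D + b*(1 - 1/n)*D^2` with per-domain dose `D = n*p*zF`.
#' The `1 - 1/n` factor is the dispersion quotient of the Binomial event
#' count; at `n = 1` only the linear term survives, and as `n` grows the
#' Poisson linear-quadratic form is recovered.
#'
#' @inheritParams simulate_domain_lethality
#' @return Mean lethal lesions per domain.
#' @export
domain_lethality_closed_form <- function(n, p, spectrum, a, b) {
  .assert_scalar_num(n, "n", lower = 0)
  .assert_scalar_num(p, "p", lower = 0, upper = 1)
  D <- n * p * spectrum$zF
  if (n == 0) return(0)
  (a + b * spectrum$zD) * D + b * (1 - 1 / n) * D^2
}
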