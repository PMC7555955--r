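---
title: "Microdosimetric kinetic modelling of survival in mixed radiation fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdosimetric kinetic modelling of survival in mixed radiation fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmix)
```

## The model

The microdosimetric kinetic model (MKM) pictures the cell nucleus as a
collection of small spherical *domains* (radius $r_d$, a few tenths of a
micrometre) inside a spherical nucleus (radius $r_n$, canonically 3.0 µm).
An *event* is everything one particle track deposits in one domain.  Given a
specific energy $z$ (Gy) in a domain, the mean number of lethal lesions is
linear-quadratic, $a z + b z^2$: the linear part from single-track damage,
the quadratic part from pairwise combination of sublethal lesions within the
domain.  Summed over the $N_d$ domains of a nucleus this produces the
familiar photon coefficients $\alpha_0 = N_d a$ and $\beta_0 = N_d b$.

When event counts per domain are Poisson — the implicit assumption of the
original MKM — averaging over domains yields the linear-quadratic survival
curve.  The point of this package is the low-dose, high-LET regime where
that assumption fails.  A track of LET $y_F$ deposits, on average,

$$z_{F,n} = \frac{0.1602\, y_F}{\rho \pi r_n^2} \quad \text{(Gy)}$$

per traversal of the nucleus, so a dose $D$ corresponds to only
$n = D / z_{F,n}$ tracks.  Event counts per domain are then binomial with at
most $n$ trials, and the quadratic term of the mean lesion count acquires
the factor

$$\frac{\sum_i (i^2 - i)\phi_i}{(\sum_i i \phi_i)^2} = 1 - \frac{1}{n},$$

which vanishes at $n = 1$.  Survival is therefore *purely exponential* up to
the threshold dose $D = z_{F,n}$ and linear-quadratic beyond it:

$$S(D) = \begin{cases}
 e^{-(\alpha_0+\beta_0 z_D) f_s D} & D \le z_{F,n}\\[2pt]
 S(z_{F,n})\, e^{-\left[(\alpha_0+\beta_0 (z_D - z_{F,n})) f_s (D-z_{F,n})
   + \beta_0 (D-z_{F,n})^2\right]} & D > z_{F,n}.
\end{cases}$$

Here $z_D$ is the dose-average specific energy per event in a *domain*
(it boosts the effective linear coefficient of densely ionising tracks) and
$f_s \in (0,1]$ is the overkill saturation factor

$$f_s = \frac{1-e^{-x}}{x}, \qquad
  x = (\alpha_0+\beta_0 z_D) z_{D,n} + \beta_0 z_{D,n}^2,$$

with $z_{D,n}$ the dose-average specific energy per event in the nucleus.
`survival_modified_mkm()` implements the piecewise curve,
`survival_original_mkm()` the Poisson (all-dose LQ) variant, and
`survival_lq()` the plain photon baseline.  At 86 keV/µm and $r_n = 3$ µm
the threshold is `r round(specific_energy_per_event(86, 3), 3)` Gy — a
clinically relevant dose, which is why the linear onset matters for ions
but is negligible for X-rays ($z_{F,n} = 0$ by convention, collapsing the
model to plain LQ).

Note one structural subtlety, implemented as printed: the post-threshold
branch restarts its quadratic term at $D - z_{F,n}$, so the curve is *not*
$\exp(-\langle L_n\rangle)$ of the continuous lesion-count expression
returned by `lethal_lesion_mean()`; the two differ by
$2\beta_0 z_{F,n}(D - z_{F,n})$ in $\ln S$ beyond the threshold.  Both
quantities are exposed because each is the authoritative form of its own
equation.

## Parameters and defaults

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `alpha0`, `beta0` | Gy⁻¹, Gy⁻² | — | photon LQ fit of the cell line |
| `rn` | µm | 3.0 | nucleus radius (average mammalian cell) |
| `rd` | µm | derived | domain radius, $(0.194/(\alpha/\beta)_x)^{1/3}$ |
| `density` | g/cm³ | 1.0 | liquid water |
| `yF`, `yD` | keV/µm | `yD = yF` | frequency-/dose-average lineal energy |
| `sigma_lnS` | — | 0.1 | generator noise on $\ln S$ |

The domain-radius relation is implemented in the *division* form above: it
reproduces all four published domain radii within 1 % (e.g. 0.2957 µm for
$\alpha_x = 0.195$, $\beta_x = 0.026$), whereas the multiplicative variant
that circulates in print does not reproduce any of them.  Likewise the
energy conversion uses the exact constant 0.1602 rather than the rounded
per-LET coefficient 0.0057 Gy/(keV/µm), so that results at other radii stay
consistent; the 0.0057 relation is recovered to two significant figures at
$r_n = 3$ µm.  Setting `yD = yF` is the monoenergetic track-segment
approximation; measured or computed dose-average quantities can be passed
as overrides (`zD`, `zD_n`, `zF_n`).

## Mixtures

For a simultaneous exposure with dose fractions $\omega_\uparrow$ (high
LET) and $\omega_\downarrow$ (low LET), dual-radiation-action mixing gives
single-field coefficients

$$\alpha_c = \omega_\uparrow \alpha_\uparrow + \omega_\downarrow
\alpha_\downarrow, \qquad
\beta_c = \left(\omega_\uparrow\sqrt{\beta_\uparrow} +
\omega_\downarrow\sqrt{\beta_\downarrow}\right)^2,$$

where each component's $\alpha$ is its saturated MKM linear coefficient
$(\alpha_0+\beta_0 z_D) f_s$ and both $\beta$s are the cell's $\beta_0$.
The radical forms are used throughout — they are the only dimensionally
consistent ones (some printed variants omit the radicals).  Two hypotheses
are provided:

* **Independent action** (`survival_mixed_independent()`): each component
  keeps its own event statistics.  Three regimes in total dose, with the
  high-LET quadratic term absent below $z_{F,n,\uparrow}$ and the
  mid-regime quadratic weight $\omega_\downarrow^2 \beta_\downarrow$.  The
  connecting constant at $z_{F,n,\uparrow}$ uses that same weight — the
  only choice that keeps $\ln S$ continuous (a printed variant with
  $\beta_\downarrow$ breaks continuity).
* **Combined action** (`survival_mixed_combined()`): the components pool
  tracks, so the effective per-track energy is the weighted harmonic mean
  $z_{F,n,c} = (\sum_i \omega_i / z_{F,n,i})^{-1}$.  With an X-ray
  component ($z_{F,n} = 0$) this is zero at any admixture: the linear
  segment disappears entirely and quadratic action starts at the origin.
  This is the synergy mechanism — the low-LET field's abundant tracks
  Poissonise the high-LET component's event statistics early.

With an X-ray low component the combined curve lies at or below the
independent one at every dose, which the test suite verifies over random
parameter draws.  Three boundary behaviours deserve mention, all asserted
as written in the tests:

* With a *general* low component ($z_{F,n,\downarrow} > 0$) the combined
  curve stays linear on $(z_{F,n,\downarrow}, z_{F,n,c}]$ while the
  independent one is already quadratic there, locally reversing the
  inequality; the model's intended use (a photon reference field) is not
  affected.
* As $\omega_\uparrow \to 1$ the independent curve matches the single-field
  piecewise curve exactly on $[0, z_{F,n,\uparrow}]$; beyond the threshold
  it keeps $\alpha_c$ rather than the $(z_D - z_{F,n})$-corrected
  coefficient, a small residual inherited from the printed equations.  The
  combined curve with an X-ray admixture tends to the *original* (Poisson)
  MKM curve instead, since its threshold stays at zero.
* At $\omega_\uparrow = 0$ exactly, the absent component's threshold is
  dropped, so the mixture is identically the low-only curve.  (The
  piecewise formula evaluated naively would still restart its quadratic at
  the phantom threshold.)

For **sequential** courses separated by too little time for repair,
sublethal lesions from a first course of dose $D_1$ (quadratic coefficient
$\beta_1$) sensitise the second course's linear coefficient:
$\alpha_{2,seq} = \alpha_2 + 2\sqrt{\beta_1\beta_2}\, D_1$
(`sequential_alpha()`).  When the low-LET course comes first its tracks
have already Poissonised the domains, so the high-LET second course starts
quadratic immediately (its linear-only regime is suppressed); when the
high-LET course comes first it retains its own linear opening segment and
the subsequent X-ray course is standard LQ with the sensitised
$\alpha_{2,seq}$ (`survival_sequential()`).

## Event statistics and the Monte-Carlo oracle

`event_count_distribution()` and `dispersion_quotient()` expose the
binomial machinery directly; the quotient equals $1 - 1/n$ for every
interaction probability $p$, which the suite checks to $10^{-12}$ over
random $(n, p)$.  `simulate_domain_lethality()` is a brute-force simulator
used as an independent oracle: per domain it draws an event count from
Binomial($n$, $p$), sums that many single-event energies and scores
$a z + b z^2$.  Only the first two moments of the per-event energy enter
the closed forms, so the sampling kernel is a convention; the default is a
gamma distribution matched to (mean $z_F$, variance $V_{z1}$), with a
lognormal alternative (both positive-support; a published identity
equating $\langle q^2\rangle$ with $V_q + \langle q^2\rangle$ is an
evident typo for the standard decomposition
$\langle q^2 \rangle = V_q + \langle q \rangle^2$, which is what the code
uses).  Seeds are explicit arguments everywhere; nothing touches the
global random state (`withr::with_seed` scoping).

## Fitting and synthetic data

`fit_lq()` linearises $-\ln S = \alpha D + \beta D^2$ and solves it by
least squares through the origin, unweighted by default with an optional
$1/\mathrm{sd}^2$ weighting (whether published fits were weighted is
usually unstated).  Both coefficients are constrained non-negative by
projection — clip at zero, refit the other — because they are rates.  The
coefficient of determination is computed on $\ln S$, the scale on which
the model is linear.  `generate_survival_dataset()` produces data from any
model curve with multiplicative lognormal noise on $S$ (normal on
$\ln S$, default $\sigma_{\ln S} = 0.1$, typical clonogenic scatter).
Observations may exceed 1 and are deliberately not clipped.  The generator
emulates independent per-point lognormal scatter only: it does not model
colony-counting (plating-efficiency) statistics, dose-dependent error
bars, or inter-experiment systematics, so passing recovery tests show
estimator correctness under the stated noise model, not robustness to
every feature of real assay data.

## Numerical choices

* $(1-e^{-x})/x$ switches to the four-term Taylor series below
  $x = 10^{-6}$; the two routes agree to $10^{-12}$ across the guard.
* Curve tabulations insert the exact threshold doses into the dose grid so
  continuity ($|\Delta \ln S| < 10^{-9}$) is testable on the emitted rows.
* Stochastic checks use a 3-standard-error tolerance with $10^5$ simulated
  domains; parameter-recovery checks use 200 replicate fits of 8-dose
  datasets at $\sigma_{\ln S} = 0.1$.  These sizes make every stochastic
  assertion decisive at the chosen tolerances while the full suite runs in
  seconds.
* CSV output uses a fixed dialect (comma, dot decimal, mandatory header,
  `#` metadata lines); units are fixed at Gy, keV/µm, µm with no
  autodetection, since silent unit errors are the dominant failure mode in
  dose modelling.

## Worked example

```{r example}
v79 <- cell_model(alpha0 = 0.195, beta0 = 0.026)   # rd derived: 0.296 um
ar <- radiation_quality("Ar", yF = 86, cell = v79) # zF_n = 0.487 Gy
survival_curve(v79, ar, seq(0, 3, by = 0.5))

both <- compare_mixture_hypotheses(ar, xray_quality(), omega_high = 0.2,
                                   cell = v79, dose = seq(0, 6, by = 0.5))
plot_survival_curves(both)
```

## Limitations

The package deliberately excludes non-targeted (bystander) effects,
hyper-radiosensitivity/induced-radioresistance, dose-rate and repair
kinetics, track-structure simulation and microdosimetric spectrum
ingestion: `zD` is approximated geometrically from `yD` and the domain
radius unless measured values are supplied.  The fixed-nucleus relation
for `rd` assumes $r_n = 3$ µm and weakens above roughly 100–200 keV/µm,
where nucleus-size variability matters — the published Fe-56 analysis
needed $r_n = 4.5$ µm, and the built-in `table1_records()` fixture carries
that override.
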