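# Shared fixtures: the V79 photon parameters of the Ar experiment and the
# radiations built from them.

v79_ar_cell <- function() cell_model(alpha0 = 0.195, beta0 = 0.026)

ar_quality <- function(cell = v79_ar_cell()) {
  radiation_quality("Ar", yF = 86, cell = cell)
}

# Absolute jump in ln S across a threshold; eps small enough that the local
# slope contributes < 1e-9 while a wrong connecting constant shows as O(1).
lnS_jump <- function(f, z, eps = 1e-10) {
  abs(log(f(z + eps)) - log(f(z)))
}

# Random-but-reproducible draws of valid model parameters for property
# suites.  The low component is an X-ray reference field (zF_n = zD = 0),
# the setting in which the mixture hypotheses are formulated.
random_mix_case <- function() {
  alpha0 <- runif(1, 0.05, 0.4)
  beta0 <- runif(1, 0.005, 0.06)
  cell <- cell_model(alpha0, beta0)
  let <- runif(1, 30, 200)
  list(
    cell = cell,
    high = radiation_quality("ion", yF = let, cell = cell),
    low = xray_quality(),
    omega_high = runif(1, 0.05, 0.95)
  )
}
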