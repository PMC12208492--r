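# Shared oracles and canonical objects for the test suite.

# independent oracle for the harmonic-mean concentration: numerical
# quadrature of 1/c(x) over the intramembrane profile
quadrature_cbar <- function(ion, V, constants = phys_constants()) {
  f <- function(xi) 1 / intramembrane_profile(ion, V, xi, constants)
  1 / stats::integrate(f, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
}

# canonical physiological ions at the Table-level steady state
std_K <- function() ion_species("K", +1, c_in = 96.83, c_out = 3.17, sigma = 100)
std_Na <- function() ion_species("Na", +1, c_in = 23.58, c_out = 131.42, sigma = 155)
std_Cl <- function() ion_species("Cl", -1, c_in = 10.41, c_out = 134.59, sigma = 145)

# least-squares slope of an I-V table
iv_slope <- function(V, I) {
  stats::coef(stats::lm(I ~ V))[["V"]]
}

# maximum relative deviation of (V, I) from the straight line through the data
max_line_deviation <- function(V, I) {
  fit <- stats::lm(I ~ V)
  max(abs(stats::resid(fit))) / max(abs(I))
}
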