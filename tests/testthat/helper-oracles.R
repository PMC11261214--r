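# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's fast paths (convolution tables,
# compiled kernels) so they can serve as references.

# reference TPC shape in plain R (same definition as the compiled one)
ref_shape <- function(u, dmin, dmax, flank = 2.5) {
  cc <- exp(-flank^2)
  out <- numeric(length(u))
  inside <- u > -dmin & u < dmax
  sig <- ifelse(u < 0, dmin / flank, dmax / flank)
  v <- (exp(-(u / sig)^2) - cc) / (1 - cc)
  out[inside] <- pmax(v[inside], 0)
  out
}

# brute-force double quadrature of E_{zg, ze}[f(zg + ze)] on fine grids:
# trapezoid over the tabulated breeding-value density times trapezoid
# over a fine Normal(0, var_e) grid
brute_mean_rate <- function(dist, var_e, f, n_e = 4001, span = 8) {
  ze <- seq(-span * sqrt(var_e), span * sqrt(var_e), length.out = n_e)
  we <- dnorm(ze, 0, sqrt(var_e))
  we <- we / evorescue:::trapz_uniform(we, ze[2] - ze[1])
  inner <- vapply(dist$grid, function(zg) {
    evorescue:::trapz_uniform(f(zg + ze) * we, ze[2] - ze[1])
  }, numeric(1))
  evorescue:::bv_integrate(dist, inner)
}

quick_config <- function(...) default_config(...)

# a small Gaussian breeding-value distribution fixture
gauss_dist <- function(mean = 20, var = 0.3, n = 601) {
  bv_dist_normal(mean, var, n = n)
}
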