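# Independent oracles and fixture builders used across the test files.

# Adaptive-quadrature oracle for the CEGS mixture PMF, independent of the
# package's trapezoidal rule. The fixed split points keep stats::integrate
# from missing the near-zero spike that carries the mass for large counts.
cegs_pmf_oracle <- function(x, gamma, lam, convention = "frechet") {
  f <- function(E) {
    s <- switch(convention,
                "frechet" = log(E) / gamma - log(lam),
                "weibull" = log(lam) - gamma * log(E),
                "weibull-complement" = gamma * log(E) - log(lam))
    exp(-E + x * stats::plogis(-s, log.p = TRUE) + stats::plogis(s, log.p = TRUE))
  }
  total_with_cuts(f, convention, gamma, lam, x)
}

# Shared split-point integration: fixed cuts resolve the near-zero spike, and
# under the "weibull" convention extra cuts bracket the large-E saddle point
# E* = (gamma * lam * x)^(1/(gamma+1)) where the mass for large counts sits.
total_with_cuts <- function(f, convention, gamma, lam, x) {
  cuts <- c(0, 1e-12, 1e-8, 1e-5, 1e-3, 0.1, 1, 10, 60)
  if (convention == "weibull" && gamma > 0 && x > 0) {
    estar <- (gamma * lam * x)^(1 / (gamma + 1))
    cuts <- sort(unique(c(cuts, estar * c(0.5, 1, 2, 4))))
  }
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(f, cuts[i], cuts[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 0,
                                      subdivisions = 400L)$value
  }
  total + stats::integrate(f, cuts[length(cuts)], Inf, rel.tol = 1e-9)$value
}

# Geometric-tail mass P(X > x0) = E[(1 - p)^(x0 + 1)]: the same integrand
# without the trailing p factor.
cegs_tail_mass <- function(x0, gamma, lam, convention = "frechet") {
  f <- function(E) {
    s <- switch(convention,
                "frechet" = log(E) / gamma - log(lam),
                "weibull" = log(lam) - gamma * log(E),
                "weibull-complement" = gamma * log(E) - log(lam))
    exp(-E + (x0 + 1) * stats::plogis(-s, log.p = TRUE))
  }
  total_with_cuts(f, convention, gamma, lam, x0 + 1)
}

# Adaptive-quadrature oracle for the PLN PMF.
pln_pmf_oracle <- function(x, mu, sigma) {
  f <- function(z) stats::dpois(x, exp(z)) * stats::dnorm(z, mu, sigma)
  lo <- mu - 12 * sigma
  hi <- max(mu + 12 * sigma, log(x + 1) + 5)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 400L)$value
}

# Random inventory with counts drawn from a heavy-ish discrete mixture; used
# by the property-style tests.
random_counts <- function(n_max = 30L) {
  S <- sample(1:n_max, 1L)
  ceiling(exp(stats::rnorm(S, 1, 1.3)))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
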