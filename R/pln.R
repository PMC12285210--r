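#' Poisson log normal parameters
#'
#' The PLN abundance model: each species has a latent sampling rate
#' `Lambda = exp(Z)` with `Z ~ Normal(mu, sigma)`, and its observed count is
#' `Poisson(Lambda)`. `sigma = 0` degenerates to a pure Poisson with rate
#' `exp(mu)` and is accepted by the PMF and the sampler (but not by the fit,
#' which needs both parameters free).
#'
#' @param mu location of the log rate (nats); `exp(mu)` is the median rate.
#' @param sigma standard deviation of the log rate (nats), >= 0.
#' @return An object of class `"pln_params"`.
#' @export
pln_params <- function(mu, sigma) {
  mu <- check_scalar(mu, "mu")
  sigma <- check_scalar(sigma, "sigma", lower = 0)
  structure(list(mu = mu, sigma = sigma), class = "pln_params")
}

#' @export
print.pln_params <- function(x, ...) {
  cat(sprintf("PLN parameters: mu = %g, sigma = %g\n", x$mu, x$sigma))
  invisible(x)
}

# Cache of Gauss-Hermite rules, keyed by node count.
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  }
  .gh_cache[[key]]
}

# Mode z* of the log-integrand g(z) = x z - e^z - lgamma(x+1) - (z-mu)^2/(2 s^2),
# i.e. the root of x - e^z - (z - mu)/s^2 = 0, found by a vectorised, damped
# Newton iteration (g is strictly concave so the root is unique).
pln_log_mode <- function(x, mu, sigma) {
  s2 <- sigma^2
  z <- ifelse(x > 0, log(x), mu - s2 * exp(mu) / (1 + s2 * exp(mu)))
  for (i in 1:100) {
    ez <- exp(z)
    f <- x - ez - (z - mu) / s2
    fp <- ez + 1 / s2
    step <- f / fp
    step <- pmin(pmax(step, -2), 2) # damping keeps exp(z) in range
    z <- z + step
    if (max(abs(step)) < 1e-12) break
  }
  z
}

#' Poisson log normal probability mass function
#'
#' `P(x) = integral of dpois(x, exp(z)) * dnorm(z, mu, sigma) dz`, evaluated
#' by Gauss-Hermite quadrature recentred at the mode of the log-integrand and
#' accumulated in log space, so the PMF stays accurate for arbitrarily large
#' counts where the naive rule (nodes spread around `mu`) underflows.
#'
#' @param x vector of counts (integers >= 0).
#' @param params a [pln_params()] object.
#' @param n_quad number of quadrature nodes (>= 40; default 200).
#' @param log if `TRUE` return log probabilities.
#' @return numeric vector of probabilities (or log probabilities).
#' @examples
#' pln_pmf(0:5, pln_params(0, 2))
#' @export
pln_pmf <- function(x, params, n_quad = 200L, log = FALSE) {
  stopifnot(inherits(params, "pln_params"))
  x <- check_counts(x, allow_zero = TRUE, what = "x")
  n_quad <- check_scalar(n_quad, "n_quad", lower = 40)
  mu <- params$mu
  sigma <- params$sigma
  if (sigma == 0) {
    lp <- stats::dpois(x, exp(mu), log = TRUE)
    return(if (log) lp else exp(lp))
  }
  gh <- gauss_hermite(as.integer(n_quad))
  zstar <- pln_log_mode(x, mu, sigma)
  h <- exp(zstar) + 1 / sigma^2            # curvature -g'' at the mode
  half_width <- sqrt(2 / h)
  # z_ij = zstar_i + half_width_i * t_j ; log P_i = log(hw_i) + lse_j(...)
  z <- outer(half_width, gh$x) + zstar
  logi <- stats::dpois(x, exp(z), log = TRUE) +
    stats::dnorm(z, mu, sigma, log = TRUE)
  logw <- matrix(log(gh$w) + gh$x^2, nrow = length(x), ncol = length(gh$x),
                 byrow = TRUE)
  lp <- log(half_width) + row_logsumexp(logw + logi)
  if (log) lp else exp(lp)
}

#' Sample species counts from the Poisson log normal model
#'
#' Draws one latent rate `exp(Normal(mu, sigma))` per species and one Poisson
#' count per rate. Zeros are retained: they are the unobserved species of a
#' community of `pool_size` species.
#'
#' @param pool_size number of species in the community (>= 1).
#' @param params a [pln_params()] object.
#' @param seed integer seed, or `NULL` to use (and advance) the current RNG
#'   stream.
#' @return integer-valued numeric vector of length `pool_size`, zeros included.
#' @export
pln_sample <- function(pool_size, params, seed = NULL) {
  stopifnot(inherits(params, "pln_params"))
  pool_size <- check_scalar(pool_size, "pool_size", lower = 1)
  with_seed(seed, {
    rates <- exp(stats::rnorm(pool_size, params$mu, params$sigma))
    stats::rpois(pool_size, rates)
  })
}

#' Zero-truncated maximum likelihood fit of the Poisson log normal
#'
#' Maximizes the zero-truncated log-likelihood
#' `sum(log(P(x_i) / (1 - P(0))))` over `(mu, log sigma)` with Nelder-Mead
#' from three deterministic starts (log-scale method of moments, and the same
#' with `mu` shifted by -1 and +1); the best likelihood wins, ties going to
#' the smaller `sigma`. The fitted zero class `p0 = P(0)` extrapolates the
#' community's true richness as `R_hat = S / (1 - p0)`: the observed species
#' are the `1 - p0` fraction of the pool that received nonzero counts.
#'
#' The raw counts are used as-is; count compression is specific to the CEGS
#' fit (see [compress_counts()]).
#'
#' @param inv an [inventory()] or numeric vector of observed counts (>= 1).
#'   At least 3 species and 2 distinct count values are required (the model
#'   has 2 free parameters).
#' @param n_quad quadrature nodes passed to [pln_pmf()].
#' @return An object of class `"sad_fit"`; see [cegs_fit()] for the fields.
#' @examples
#' x <- pln_sample(500, pln_params(0, 1.5), seed = 1)
#' fit <- pln_fit(x[x > 0])
#' fit
#' @export
pln_fit <- function(inv, n_quad = 200L) {
  counts <- as_counts(inv)
  S <- length(counts)
  if (S < 3L) {
    stop("PLN fit requires at least 3 observed species", call. = FALSE)
  }
  if (length(unique(counts)) < 2L) {
    stop("PLN fit requires at least 2 distinct count values (all counts equal is non-identifiable)",
         call. = FALSE)
  }
  tab <- table(counts)
  u <- as.numeric(names(tab))
  m <- as.numeric(tab)
  n_eval <- 0L
  nll <- function(theta) {
    n_eval <<- n_eval + 1L
    pars <- pln_params(theta[1], exp(theta[2]))
    lp <- pln_pmf(c(0, u), pars, n_quad = n_quad, log = TRUE)
    lp0 <- lp[1L]
    if (!is.finite(lp0) || lp0 >= 0) return(1e10)
    val <- sum(m * lp[-1L]) - S * log1p(-exp(lp0))
    if (!is.finite(val)) return(1e10)
    -val
  }
  logx <- log(counts)
  mu0 <- mean(logx)
  s0 <- max(stats::sd(logx), 0.25)
  starts <- list(c(mu0, log(s0)), c(mu0 - 1, log(s0)), c(mu0 + 1, log(s0)))
  fits <- lapply(starts, function(st) {
    stats::optim(st, nll, method = "Nelder-Mead",
                 control = list(maxit = 1000L, reltol = 1e-10))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  sigs <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- order(vals, sigs)[1L]   # best likelihood; ties -> smaller sigma
  f <- fits[[best]]
  pars <- pln_params(f$par[1], exp(f$par[2]))
  p0 <- pln_pmf(0, pars, n_quad = n_quad)
  new_sad_fit(model = "pln", params = pars, loglik = -f$value, p0 = p0,
              S_obs = S, converged = (f$convergence == 0L), n_eval = n_eval)
}
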