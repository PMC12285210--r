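test_that("stopping probabilities follow their defining formulas", {
  pars <- cegs_params(2, 1)
  for (conv in c("frechet", "weibull", "weibull-complement")) {
    expect_equal(cegs_stop_prob(1, pars, conv), 0.5)  # E = 1, lam = 1
  }
  expect_equal(cegs_stop_prob(5, cegs_params(0, 1), "weibull"), 0.5)
  expect_equal(cegs_stop_prob(2, cegs_params(2, 4), "weibull"), 0.5)
  expect_equal(cegs_stop_prob(4, cegs_params(2, 3), "frechet"), 2 / 5)
  expect_equal(cegs_stop_prob(2, cegs_params(2, 4), "weibull-complement"),
               0.5)
  expect_error(cegs_stop_prob(0, pars), "positive")
  expect_error(cegs_stop_prob(-1, pars), "positive")
  expect_error(cegs_stop_prob(1, cegs_params(0, 1), "frechet"), "gamma > 0")
})

test_that("the zero class matches closed forms under the literal convention", {
  # gamma = 0: constant integrand, exactly lam/(1+lam)
  expect_equal(cegs_p0(cegs_params(0, 1), convention = "weibull"), 0.5,
               tolerance = 1e-10)
  expect_equal(cegs_p0(cegs_params(0, 3), convention = "weibull"), 0.75,
               tolerance = 1e-10)
  # gamma = 1: e * E1(1); gamma = 2: Ci(1) sin(1) + (pi/2 - Si(1)) cos(1)
  expect_equal(cegs_p0(cegs_params(1, 1), convention = "weibull"),
               exp(1) * pracma::expint_E1(1), tolerance = 1e-9)
  expect_equal(cegs_p0(cegs_params(2, 1), convention = "weibull"),
               pracma::Ci(1) * sin(1) + (pi / 2 - pracma::Si(1)) * cos(1),
               tolerance = 1e-9)
})

test_that("the zero class matches adaptive quadrature under every convention", {
  for (conv in c("frechet", "weibull", "weibull-complement")) {
    for (gl in list(c(0.5, 4), c(1, 1), c(2, 1), c(4, 0.25))) {
      expect_equal(cegs_p0(cegs_params(gl[1], gl[2]), convention = conv),
                   cegs_pmf_oracle(0, gl[1], gl[2], conv), tolerance = 1e-8)
    }
  }
})

test_that("gamma = 0 collapses the PMF to an exact geometric distribution", {
  for (lam in c(0.25, 1, 4)) {
    p <- lam / (1 + lam)
    expect_equal(cegs_pmf(0:20, cegs_params(0, lam), convention = "weibull"),
                 p * (1 - p)^(0:20), tolerance = 1e-8)
  }
})

test_that("the CEGS PMF matches adaptive quadrature including far tails", {
  for (conv in c("frechet", "weibull", "weibull-complement")) {
    for (gl in list(c(0.5, 4), c(2, 1), c(4, 0.25))) {
      for (x in c(1, 5, 50, 500, 5000)) {
        orc <- cegs_pmf_oracle(x, gl[1], gl[2], conv)
        if (orc > 1e-250) {
          mine <- cegs_pmf(x, cegs_params(gl[1], gl[2]), convention = conv)
          expect_lt(abs(mine - orc) / orc, 1e-7)
        }
      }
    }
  }
})

test_that("P(0) from the PMF equals cegs_p0", {
  for (conv in c("frechet", "weibull")) {
    pars <- cegs_params(2, 1)
    expect_equal(cegs_pmf(0, pars, convention = conv),
                 cegs_p0(pars, convention = conv))
  }
})

test_that("the PMF is normalized after truncation correction across the grids", {
  X <- 2000
  grids <- list(weibull = expand.grid(g = c(0, 0.5, 1, 2, 4),
                                      l = c(0.25, 1, 4)),
                frechet = expand.grid(g = c(0.5, 1, 2, 4),
                                      l = c(0.25, 1, 4)))
  for (conv in names(grids)) {
    g <- grids[[conv]]
    for (i in seq_len(nrow(g))) {
      pars <- cegs_params(g$g[i], g$l[i])
      total <- sum(cegs_pmf(0:X, pars, convention = conv)) +
        cegs_tail_mass(X, g$g[i], g$l[i], conv)
      expect_lt(abs(total - 1), 1e-6)
    }
  }
})

test_that("the zero class grows with lam under the literal convention", {
  lams <- c(0.25, 0.5, 1, 2, 4, 8)
  for (g in c(0.5, 2)) {
    p0 <- vapply(lams, function(l) {
      cegs_p0(cegs_params(g, l), convention = "weibull")
    }, numeric(1))
    expect_true(all(diff(p0) > 0))
  }
})

test_that("count compression replaces the top two with the second-lowest class", {
  expect_equal(compress_counts(c(1, 1, 3, 5, 7)), c(1, 1, 3, 3, 3))
  expect_equal(compress_counts(c(1, 2, 3, 4, 5)), c(1, 2, 2, 2, 3))
  expect_equal(compress_counts(c(1, 1, 2, 2, 3)), c(1, 1, 2, 2, 2))
  expect_equal(compress_counts(c(7, 5, 3, 1, 1)), c(1, 1, 3, 3, 3)) # order-free
  expect_error(compress_counts(c(1, 1, 2, 2)), "5 species")
  expect_error(compress_counts(c(2, 2, 2, 3, 3, 3)), "3 distinct")
  set.seed(31)
  for (i in 1:20) {
    n <- random_counts() + 0
    if (length(n) < 5 || length(unique(n)) < 3) next
    out <- compress_counts(n)
    expect_equal(length(out), length(n))
    expect_false(is.unsorted(out))
    expect_true(all(out %in% n))          # values come from the input classes
    # the new maximum is the third-largest original or the replacement class
    expect_equal(max(out), max(sort(n)[length(n) - 2], sort(unique(n))[2]))
  }
})

test_that("sampler and PMF agree in distribution", {
  pars <- cegs_params(2, 1)
  x <- cegs_sample(2e5, pars, seed = 33)
  xs <- 0:3000
  pm <- cegs_pmf(xs, pars)
  emp <- tabulate(pmin(x, 3001) + 1, nbins = 3002) / 2e5
  tv <- 0.5 * (sum(abs(emp[1:3001] - pm)) + abs(emp[3002] - (1 - sum(pm))))
  expect_lt(tv, 0.01)
  expect_identical(cegs_sample(50, pars, seed = 1),
                   cegs_sample(50, pars, seed = 1))
})

test_that("gamma = 0 sampling is iid geometric with the closed-form mean", {
  x <- cegs_sample(2e5, cegs_params(0, 1), seed = 34, convention = "weibull")
  expect_lt(abs(mean(x) - 1), 3 * sqrt(2 / 2e5))  # mean (1-p)/p = 1, var 2
})

test_that("CEGS fitting enforces its preconditions and invariants", {
  expect_error(cegs_fit(c(1, 2, 3, 4)), "5 species")
  expect_error(cegs_fit(c(2, 2, 3, 3, 2, 3)), "3 distinct")
  x <- cegs_sample(600, cegs_params(2, 1), seed = 35)
  f <- cegs_fit(x[x > 0])
  expect_gte(f$R_hat, f$S_obs)
  expect_true(f$p0 >= 0 && f$p0 < 1)
  expect_true(f$converged)
  # deterministic: same data, same answer
  f2 <- cegs_fit(x[x > 0])
  expect_equal(coef(f), coef(f2))
  expect_equal(f$loglik, f2$loglik)
})

test_that("compression is a preprocessing step that never changes S_obs", {
  x <- cegs_sample(600, cegs_params(2, 1), seed = 36)
  x <- x[x > 0]
  f <- cegs_fit(x)
  expect_equal(f$S_obs, length(x))
  raw <- cegs_fit(x, compress = FALSE)
  expect_equal(raw$S_obs, length(x))
})

test_that("CEGS fits close the loop on data they generated", {
  res <- t(vapply(1:3, function(s) {
    x <- cegs_sample(1200, cegs_params(2, 1), seed = 40 + s)
    f <- cegs_fit(x[x > 0])
    c(coef(f), R = f$R_hat)
  }, numeric(3)))
  expect_lt(abs(median(res[, "gamma"]) / 2 - 1), 0.3)
  expect_lt(abs(median(res[, "lam"]) / 1 - 1), 0.3)
  expect_lt(abs(median(res[, "R"]) / 1200 - 1), 0.15)
})
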