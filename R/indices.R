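#' Shannon entropy of a count vector
#'
#' `H = -sum(p_i * log(p_i))` with `p_i = n_i / N`, in nats (natural
#' logarithms are used throughout the package). A single-species inventory has
#' `H = 0`. `exp(H)` is the Hill number of order 1, in species equivalents.
#'
#' @param counts an [inventory()] or a numeric vector of counts >= 1.
#' @return Shannon's H in nats.
#' @examples
#' exp(shannon_H(c(1, 1, 1, 10)))  # 2.21 species equivalents
#' @export
shannon_H <- function(counts) {
  n <- as_counts(counts)
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Simpson concentration of a count vector
#'
#' The plug-in form `D = sum(p_i^2)`, the probability that two individuals
#' drawn with replacement belong to the same species. Its reciprocal `1/D` is
#' the Hill number of order 2. No small-sample (Hurlbert-type) correction is
#' applied: the plug-in form is the one consistent with the Hill-number
#' algebra used elsewhere in the package.
#'
#' @inheritParams shannon_H
#' @return Simpson's D in (0, 1].
#' @examples
#' 1 / simpson_D(c(1, 1, 1, 1))  # 4 species equivalents
#' @export
simpson_D <- function(counts) {
  n <- as_counts(counts)
  p <- n / sum(n)
  sum(p^2)
}

#' Pielou's evenness J
#'
#' `J = H / log(S)`, in (0, 1]; equal to 1 iff all counts are equal. Undefined
#' for a single species (`log(1) = 0`), which is an error here; the profile
#' constructor [diversity_profile()] instead records `NA`.
#'
#' @inheritParams shannon_H
#' @return J, dimensionless.
#' @export
pielou_J <- function(counts) {
  n <- as_counts(counts)
  if (length(n) < 2L) {
    stop("Pielou's J requires at least 2 species (log S would be 0)",
         call. = FALSE)
  }
  shannon_H(n) / log(length(n))
}

#' Hill numbers (species equivalents of order q)
#'
#' `(sum(p_i^q))^(1/(1-q))` for real `q != 1`, with the limits `exp(H)` at
#' `q = 1`, `S` at `q = 0`, `1/max(p)` at `q = +Inf` and `1/min(p)` at
#' `q = -Inf`. Orders below 0 increasingly weight rare species and are
#' computed by the same formula. Hill numbers are non-increasing in `q`.
#'
#' @inheritParams shannon_H
#' @param q numeric vector of orders; may include `Inf` and `-Inf`.
#' @return numeric vector of species equivalents, one per `q`.
#' @examples
#' hill_number(c(1, 1, 1, 10), q = c(0, 1, 2, Inf))
#' @export
hill_number <- function(counts, q) {
  n <- as_counts(counts)
  stopifnot(is.numeric(q), length(q) >= 1L, !anyNA(q))
  p <- n / sum(n)
  lp <- log(p)
  vapply(q, function(qi) {
    if (qi == Inf) return(1 / max(p))
    if (qi == -Inf) return(1 / min(p))
    if (abs(qi - 1) < 1e-9) return(exp(-sum(p * lp)))
    # log-scale evaluation keeps large |q| finite
    exp(logsumexp(qi * lp) / (1 - qi))
  }, numeric(1))
}

#' Logged Hill ratio H + ln D
#'
#' The natural log of the ratio of the order-1 and order-2 Hill numbers,
#' `ln(exp(H) / (1/D)) = H + ln(D)`, in nats. It is >= 0, with equality iff
#' all counts are equal, and is a scale-free summary of how far the count
#' distribution departs from uniformity.
#'
#' @inheritParams shannon_H
#' @return H + ln D in nats (>= 0).
#' @export
hill_ratio <- function(counts) {
  n <- as_counts(counts)
  shannon_H(n) + log(simpson_D(n))
}

#' Fisher's alpha and the log-series scale parameter
#'
#' Solves `S = alpha * log(1 + N / alpha)` for `alpha` by bracketed
#' root-finding (relative tolerance 1e-10) and returns the log-series scale
#' `x = N / (N + alpha)` alongside. `alpha` diverges as `S` approaches `N`,
#' so `N > S >= 1` is required.
#'
#' @param S observed species count (>= 1).
#' @param N total individual count (> S).
#' @return named numeric vector `c(alpha = ..., x_ls = ...)`.
#' @examples
#' fishers_alpha(S = 4, N = 13)
#' @export
fishers_alpha <- function(S, N) {
  S <- check_scalar(S, "S", lower = 1)
  N <- check_scalar(N, "N", lower = 1)
  if (S >= N) {
    stop("Fisher's alpha requires N > S: it diverges as S approaches N",
         call. = FALSE)
  }
  # g(alpha) = alpha log(1 + N/alpha) - S is increasing from -S to N - S > 0
  g <- function(a) a * log1p(N / a) - S
  upper <- max(S, 1)
  while (g(upper) < 0) upper <- upper * 2
  root <- stats::uniroot(g, lower = 1e-12, upper = upper, tol = 1e-14,
                         maxiter = 2000L)
  alpha <- root$root
  # polish with a Newton step for full relative precision
  for (i in 1:3) {
    fp <- log1p(N / alpha) - N / (alpha + N)
    alpha <- alpha - g(alpha) / fp
  }
  c(alpha = alpha, x_ls = N / (N + alpha))
}

#' All diversity statistics for one inventory
#'
#' Computes the full set of per-inventory statistics: richness `S`, sample
#' size `N`, Shannon's `H` and `expH`, Simpson's `D` and `invD`, Pielou's
#' `J`, Berger-Parker dominance `d` (the proportional abundance of the most
#' common species), the logged Hill ratio `H + ln D`, and Fisher's `alpha`
#' with the log-series scale `x_ls`. Statistics whose preconditions fail
#' (`J` for S < 2; `alpha` and `x_ls` for S >= N) are reported as `NA`,
#' never silently as 0.
#'
#' @param inv an [inventory()] or a numeric vector of counts >= 1.
#' @return A one-row `data.frame` with columns `site`, `S`, `N`, `H`, `expH`,
#'   `D`, `invD`, `J`, `d`, `hill_ratio`, `alpha`, `x_ls`.
#' @examples
#' diversity_profile(c(1, 1, 1, 10))
#' @export
diversity_profile <- function(inv) {
  n <- as_counts(inv)
  site <- if (inherits(inv, "inventory")) inv$site_id else NA_character_
  S <- length(n)
  N <- sum(n)
  H <- shannon_H(n)
  D <- simpson_D(n)
  J <- if (S >= 2L) H / log(S) else NA_real_
  if (N > S) {
    fa <- fishers_alpha(S, N)
    alpha <- unname(fa["alpha"])
    x_ls <- unname(fa["x_ls"])
  } else {
    alpha <- NA_real_
    x_ls <- NA_real_
  }
  data.frame(site = site, S = S, N = N, H = H, expH = exp(H), D = D,
             invD = 1 / D, J = J, d = max(n) / N, hill_ratio = H + log(D),
             alpha = alpha, x_ls = x_ls, stringsAsFactors = FALSE)
}

#' Diversity profiles for a collection of inventories
#'
#' @param inventories a list of [inventory()] objects.
#' @return A `data.frame` with one [diversity_profile()] row per inventory.
#' @export
diversity_profiles <- function(inventories) {
  if (inherits(inventories, "inventory")) inventories <- list(inventories)
  do.call(rbind, lapply(inventories, diversity_profile))
}
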