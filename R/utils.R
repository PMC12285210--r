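# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# go through this so nothing ever consumes or perturbs global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

# Row-wise log(sum(exp(m))) with the usual max shift; m is a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Validate a vector of observed species counts: integers >= 1 (or >= 0 when
# zeros are allowed, e.g. raw sampler output).
check_counts <- function(counts, allow_zero = FALSE, allow_empty = FALSE,
                         what = "counts") {
  if (!is.numeric(counts)) {
    stop(sprintf("`%s` must be a numeric vector of integer counts", what),
         call. = FALSE)
  }
  if (!allow_empty && length(counts) == 0L) {
    stop(sprintf("`%s` is empty: at least one species count is required", what),
         call. = FALSE)
  }
  if (anyNA(counts)) {
    stop(sprintf("`%s` contains missing values", what), call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop(sprintf("`%s` must contain whole numbers", what), call. = FALSE)
  }
  lo <- if (allow_zero) 0 else 1
  if (any(counts < lo)) {
    stop(sprintf("`%s` must be >= %d (zero-count species are unobserved)",
                 what, lo), call. = FALSE)
  }
  counts <- round(counts)          # keep any species names
  storage.mode(counts) <- "double"
  counts
}

check_scalar <- function(x, what, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", what, x), call. = FALSE)
  }
  as.numeric(x)
}
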