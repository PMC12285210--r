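#' Remove the dominant species from an inventory
#'
#' Drops exactly one species with the maximal count (the first such species
#' in stored order when the maximum is tied), leaving all other counts
#' unchanged. Recomputing indices before and after quantifies how strongly
#' each statistic is controlled by a single count.
#'
#' @param inv an [inventory()] or numeric vector of counts with S >= 2.
#' @return object of the same kind as the input, with one species removed.
#' @examples
#' remove_dominant(c(1, 1, 1, 10))
#' @export
remove_dominant <- function(inv) {
  n <- as_counts(inv)
  if (length(n) < 2L) {
    stop("removing the dominant requires at least 2 species", call. = FALSE)
  }
  drop <- which.max(n)  # first maximal species in stored order
  if (inherits(inv, "inventory")) {
    out <- inv
    out$counts <- inv$counts[-drop]
    out
  } else {
    n[-drop]
  }
}

#' Bootstrap an inventory's count list
#'
#' Resamples the multiset of counts fully and with replacement: S counts are
#' drawn from the original S counts, so the number of species is fixed and
#' the expected total sample size is unchanged. A statistic robust to the
#' shape of single counts should be (on average) unchanged by this.
#'
#' @param inv an [inventory()] or numeric vector of counts.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return object of the same kind as the input with resampled counts.
#' @export
bootstrap_inventory <- function(inv, seed = NULL) {
  n <- as_counts(inv)
  res <- with_seed(seed, n[sample.int(length(n), length(n), replace = TRUE)])
  if (inherits(inv, "inventory")) {
    out <- inv
    out$counts <- unname(res)
    out
  } else {
    unname(res)
  }
}

#' Sum of reciprocal counts
#'
#' `sum(1 / n_i)`, a similarity key dominated by the rare species: inventories
#' with near-equal reciprocal sums hold similar numbers of rare species while
#' their common species are largely ignored.
#'
#' @param counts an [inventory()] or numeric vector of counts >= 1.
#' @return the reciprocal sum (dimensionless).
#' @examples
#' reciprocal_sum(c(1, 2, 10))    # 1.6
#' reciprocal_sum(c(1, 2, 1000))  # 1.501
#' @export
reciprocal_sum <- function(counts) {
  sum(1 / as_counts(counts))
}

#' Match inventories by reciprocal-sum similarity
#'
#' Pairs every inventory (the focal) with the distinct inventory whose
#' reciprocal sum is nearest (smallest `|r_focal - r_partner|`), ties broken
#' by the lower index. Partners may be reused: matching is nearest-neighbour,
#' not one-to-one.
#'
#' @param inventories a list of at least 2 inventories (or count vectors).
#' @return An object of class `"pair_set"`: a list with `pairs` (data.frame
#'   of `focal`, `partner` indices) and `r_values`.
#' @export
match_pairs <- function(inventories) {
  if (length(inventories) < 2L) {
    stop("pair matching requires at least 2 inventories", call. = FALSE)
  }
  r <- vapply(inventories, reciprocal_sum, numeric(1))
  k <- length(r)
  partner <- integer(k)
  for (i in seq_len(k)) {
    d <- abs(r - r[i])
    d[i] <- Inf
    partner[i] <- which.min(d)  # which.min takes the lowest index on ties
  }
  structure(
    list(pairs = data.frame(focal = seq_len(k), partner = partner),
         r_values = unname(r)),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("Reciprocal-sum pair set: %d inventories\n", nrow(x$pairs)))
  print(utils::head(cbind(x$pairs, r_focal = x$r_values[x$pairs$focal],
                          r_partner = x$r_values[x$pairs$partner]), 10L))
  if (nrow(x$pairs) > 10L) cat("...\n")
  invisible(x)
}

#' Summarise original-versus-manipulated metric pairs
#'
#' For a set of (original, manipulated) metric values — e.g. an index before
#' and after bootstrapping — computes the Spearman rank correlation (average
#' ranks on ties) and the fraction of non-tied pairs in which the manipulated
#' value exceeds the original. Exact ties are excluded from both the
#' numerator and the denominator of the fraction; if every pair is tied the
#' fraction is `NA`. A rank correlation is reported because these
#' relationships are typically non-linear.
#'
#' @param original,manipulated numeric vectors of equal length; at least 3
#'   pairs must be finite in both.
#' @return list with `spearman_rho`, `fraction_above` and `n_pairs`.
#' @export
paired_metric_summary <- function(original, manipulated) {
  stopifnot(is.numeric(original), is.numeric(manipulated),
            length(original) == length(manipulated))
  ok <- is.finite(original) & is.finite(manipulated)
  x <- original[ok]
  y <- manipulated[ok]
  if (length(x) < 3L) {
    stop("at least 3 finite (original, manipulated) pairs are required",
         call. = FALSE)
  }
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y, method = "spearman")
  }
  untied <- y != x
  frac <- if (any(untied)) sum(y > x) / sum(untied) else NA_real_
  list(spearman_rho = rho, fraction_above = frac, n_pairs = length(x))
}

#' Latitudinal summary of a diversity metric
#'
#' Computes one metric per inventory, the sample standard deviation of its
#' natural-log values (the package's gradient-strength summary), and a
#' descriptive local-regression smooth of log metric against latitude
#' (quadratic loess, span 0.75). Inventories without a latitude or with a
#' nonpositive or missing metric value are excluded with a warning.
#'
#' @param inventories list of [inventory()] objects carrying latitudes.
#' @param metric name of a [diversity_profile()] column (default `"expH"`),
#'   or a function mapping a count vector to a positive scalar (e.g.
#'   `function(x) cegs_fit(x)$R_hat`).
#' @param span,degree loess smoothing parameters.
#' @return list with `data` (site, latitude, value), `sd_of_logs`, and
#'   `curve` (a data.frame of latitude and smoothed log-metric values).
#' @export
latitudinal_summary <- function(inventories, metric = "expH", span = 0.75,
                                degree = 2) {
  if (inherits(inventories, "inventory")) inventories <- list(inventories)
  lat <- vapply(inventories, function(z) {
    if (is.null(z$latitude)) NA_real_ else z$latitude
  }, numeric(1))
  vals <- if (is.function(metric)) {
    vapply(inventories, function(z) metric(z$counts), numeric(1))
  } else {
    prof <- diversity_profiles(inventories)
    if (!metric %in% names(prof)) {
      stop("unknown metric '", metric, "'", call. = FALSE)
    }
    prof[[metric]]
  }
  sites <- vapply(inventories, function(z) z$site_id, character(1))
  ok <- is.finite(lat) & is.finite(vals) & vals > 0
  if (any(!ok)) {
    warning(sum(!ok), " inventories excluded (missing latitude or ",
            "nonpositive/undefined metric value)", call. = FALSE)
  }
  if (sum(ok) < 5L) {
    stop("latitudinal summary requires at least 5 usable inventories",
         call. = FALSE)
  }
  df <- data.frame(site = sites[ok], latitude = lat[ok], value = vals[ok],
                   stringsAsFactors = FALSE)
  lv <- log(df$value)
  grid <- seq(min(df$latitude), max(df$latitude), length.out = 101L)
  smooth <- if (stats::sd(df$latitude) == 0) {
    rep(mean(lv), length(grid))
  } else {
    # widen the span for very small collections so the local quadratic stays
    # well-posed; unchanged for n >= 11 at the default span
    span_eff <- max(span, min(1, 8 / nrow(df)))
    lo <- stats::loess(lv ~ latitude, data = df, span = span_eff,
                       degree = degree)
    as.numeric(stats::predict(lo, newdata = data.frame(latitude = grid)))
  }
  list(data = df,
       sd_of_logs = stats::sd(lv),
       curve = data.frame(latitude = grid, log_metric = smooth))
}
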