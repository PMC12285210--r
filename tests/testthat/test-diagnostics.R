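test_that("dominant removal drops exactly one maximal species", {
  expect_equal(remove_dominant(c(1, 1, 1, 10)), c(1, 1, 1))
  expect_equal(remove_dominant(c(5, 5, 2)), c(5, 2))  # tie: first maximal
  expect_error(remove_dominant(7), "at least 2")
  inv <- inventory(c(a = 3, b = 9, c = 1), site_id = "x")
  out <- remove_dominant(inv)
  expect_s3_class(out, "inventory")
  expect_equal(out$counts, c(a = 3, c = 1))
  set.seed(51)
  for (i in 1:20) {
    n <- random_counts()
    if (length(n) < 2) next
    out <- remove_dominant(n)
    expect_equal(sum(n) - sum(out), max(n))  # N drops by the maximum exactly
    expect_lte(max(out) / sum(out), 1)
  }
})

test_that("bootstrapping fixes S and resamples from the original multiset", {
  expect_equal(bootstrap_inventory(c(5, 5, 5), seed = 1), c(5, 5, 5))
  set.seed(52)
  for (i in 1:20) {
    n <- random_counts()
    b <- bootstrap_inventory(n, seed = i)
    expect_equal(length(b), length(n))
    expect_true(all(b %in% n))
  }
  expect_identical(bootstrap_inventory(c(1, 2, 3, 9), seed = 4),
                   bootstrap_inventory(c(1, 2, 3, 9), seed = 4))
})

test_that("bootstrap draws are uniform multinomial over positions", {
  # on (1,1,1,10) the number of 10s drawn is Binomial(4, 1/4)
  n_rep <- 4000L
  k10 <- vapply(seq_len(n_rep), function(s) {
    sum(bootstrap_inventory(c(1, 1, 1, 10), seed = 1000 + s) == 10)
  }, numeric(1))
  exp_p <- dbinom(0:4, 4, 0.25)
  obs_p <- tabulate(k10 + 1, nbins = 5) / n_rep
  se <- sqrt(exp_p * (1 - exp_p) / n_rep)
  expect_true(all(abs(obs_p - exp_p) < 4 * pmax(se, 1e-4)))
})

test_that("reciprocal sums match hand arithmetic", {
  expect_equal(reciprocal_sum(c(1, 2, 10)), 1.6)
  expect_equal(reciprocal_sum(c(1, 2, 1000)), 1.501)
  expect_equal(reciprocal_sum(1), 1)
  expect_error(reciprocal_sum(numeric(0)), "empty")
})

test_that("pair matching is nearest-neighbour on reciprocal sums", {
  # r-values 1.6, 1.501, 3.0: brute force over |dr| pairs 1<->2 and 3 -> 1
  invs <- list(c(1, 2, 10), c(1, 2, 1000), c(1, 1, 1))
  ps <- match_pairs(invs)
  expect_equal(ps$r_values, c(1.6, 1.501, 3.0))
  expect_equal(ps$pairs$partner, c(2, 1, 1))
  # two inventories pair with each other
  expect_equal(match_pairs(list(c(1, 2), c(5, 5)))$pairs$partner, c(2, 1))
  # exact ties break to the lowest index
  tied <- match_pairs(list(c(2, 2), c(4, 4, 4, 4), c(1), c(2, 2)))
  expect_equal(tied$pairs$partner[2], 1)  # r = 1 for all three others
  expect_error(match_pairs(list(c(1, 2))), "at least 2")
})

test_that("pair matching commutes with relabeling", {
  set.seed(53)
  invs <- replicate(8, random_counts(), simplify = FALSE)
  base <- match_pairs(invs)$pairs$partner
  perm <- sample(8)
  permuted <- match_pairs(invs[perm])$pairs$partner
  # partner of inventory perm[i] in the permuted list is the relabeled base partner
  expect_equal(order(perm)[base[perm]], permuted)
})

test_that("paired summaries report Spearman rho and the fraction above unity", {
  v <- c(3, 1, 4, 1.5, 9, 2.6)
  s <- paired_metric_summary(v, v)
  expect_equal(s$spearman_rho, 1)
  expect_true(is.na(s$fraction_above))  # all exact ties
  rev_s <- paired_metric_summary(v, -v)
  expect_equal(rev_s$spearman_rho, -1)
  # brute-force average-rank formula on 6 points with ties
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 1, 4, 4, 6, 5)
  rho_brute <- {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(paired_metric_summary(x, y)$spearman_rho, rho_brute)
  expect_equal(paired_metric_summary(x, y)$fraction_above, 4 / 5)
  expect_error(paired_metric_summary(c(1, 2), c(2, 1)), "at least 3")
})

test_that("latitudinal summaries compute log-scale spread and a smooth curve", {
  mk <- function(S, lat, id) {
    inventory(rep(1, S), site_id = id, latitude = lat)
  }
  # constant metric: zero spread, flat curve
  invs <- lapply(1:6, function(i) mk(10, -30 + 10 * i, paste0("c", i)))
  out <- latitudinal_summary(invs, metric = "S")
  expect_equal(out$sd_of_logs, 0)
  expect_lt(diff(range(out$curve$log_metric)), 1e-10)
  # hand-computable spread: alternating metric values 1 and e^2
  invs <- lapply(1:6, function(i) {
    mk(if (i %% 2 == 0) round(exp(2)) else 1, i, paste0("a", i))
  })
  out <- latitudinal_summary(invs, metric = "S")
  expect_equal(out$sd_of_logs, sd(log(vapply(invs, function(z) {
    length(z$counts)
  }, numeric(1)))))
  # hump-shaped gradient: smoothed peak lands within 5 degrees of the truth
  lats <- seq(-60, 60, by = 2.5)
  invs <- lapply(seq_along(lats), function(i) {
    S <- 5 + round(120 * exp(-(lats[i] - 10)^2 / 800))
    mk(S, lats[i], paste0("g", i))
  })
  out <- latitudinal_summary(invs, metric = "S")
  peak <- out$curve$latitude[which.max(out$curve$log_metric)]
  expect_lt(abs(peak - 10), 5)
})

test_that("latitudinal summaries exclude unusable inventories loudly", {
  mk <- function(S, lat, id) inventory(rep(1, S), site_id = id, latitude = lat)
  invs <- c(lapply(1:5, function(i) mk(i + 4, i * 5, paste0("k", i))),
            list(inventory(c(2, 3), site_id = "nolat")))
  expect_warning(out <- latitudinal_summary(invs, metric = "S"), "excluded")
  expect_equal(nrow(out$data), 5)
  expect_error(
    suppressWarnings(latitudinal_summary(invs[1:3], metric = "S")),
    "at least 5"
  )
})
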