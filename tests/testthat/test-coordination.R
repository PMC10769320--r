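test_that("Fisher odds ratio follows the cross-product with Haldane correction", {
  res <- fisher_exact(matrix(c(10, 5, 5, 10), 2, 2, byrow = TRUE))
  expect_equal(res$odds_ratio, 4)
  # zero cell: +0.5 on every cell for the reported OR
  res0 <- fisher_exact(matrix(c(0, 5, 5, 10), 2, 2, byrow = TRUE))
  expect_equal(res0$odds_ratio, (0.5 * 10.5) / (5.5 * 5.5), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
})

test_that("Fisher p-values match hypergeometric enumeration and transpose", {
  set.seed(9)
  for (i in 1:60) {
    k <- matrix(sample(0:12, 4, replace = TRUE), 2, 2)
    if (sum(k) == 0) next
    res <- fisher_exact(k)
    expect_equal(res$p_value, enum_fisher_p(k[1, 1], k[1, 2], k[2, 1], k[2, 2]),
                 tolerance = 1e-10)
    # transpose invariance of OR and p
    rt <- fisher_exact(t(k))
    expect_equal(rt$odds_ratio, res$odds_ratio, tolerance = 1e-12)
    expect_equal(rt$p_value, res$p_value, tolerance = 1e-12)
    # agreement with the standard library test's p-value
    expect_equal(res$p_value, stats::fisher.test(k)$p.value, tolerance = 1e-9)
  }
})

test_that("co-occupancy tables tally fibers and honor accessibility", {
  df <- tibble::tibble(
    a = c(TRUE, TRUE, FALSE, FALSE), b = c(TRUE, FALSE, TRUE, FALSE),
    acc_a = TRUE, acc_b = TRUE
  )
  res <- build_cooccupancy_table(df)
  expect_equal(c(res$n11, res$n10, res$n01, res$n00), c(1, 1, 1, 1))
  expect_equal(res$p_value, 1)
  # a fiber inaccessible at element A drops out under the filter
  df$acc_a[1] <- FALSE
  res2 <- build_cooccupancy_table(df, require_accessible = TRUE)
  expect_equal(res2$n, 3)
  expect_equal(res2$n11, 0)
  # not-evaluable (NA) accessibility also excludes
  df$acc_b[2] <- NA
  expect_equal(build_cooccupancy_table(df, require_accessible = TRUE)$n, 2)
})

test_that("equal-event binning follows the greedy cumulative rule", {
  p4 <- tibble::tibble(pair_id = paste0("p", 1:4), distance = c(1, 2, 3, 4) * 1000,
                       n_sim = c(3, 3, 3, 3))
  b <- bin_pairs_equal_events(p4, 2)
  expect_equal(b$bin, c(1L, 1L, 2L, 2L))
  p_skew <- dplyr::mutate(p4, n_sim = c(6, 0, 0, 6))
  b2 <- bin_pairs_equal_events(p_skew, 2)
  expect_equal(b2$bin, c(1L, 2L, 2L, 2L))
  # beyond max_dist pairs are dropped
  b3 <- bin_pairs_equal_events(dplyr::mutate(p4, distance = c(1, 2, 3, 11) * 1000), 2)
  expect_equal(nrow(b3), 3)
  expect_warning(bin_pairs_equal_events(dplyr::mutate(p4, n_sim = 0:3), 20),
                 "fewer bins")
})

test_that("greedy binning is near the optimal contiguous partition", {
  # oracle: exhaustive search over all contiguous partitions into n_bins
  best_imbalance <- function(n_sim, n_bins) {
    np <- length(n_sim)
    cuts <- utils::combn(np - 1, n_bins - 1)
    best <- Inf
    for (j in seq_len(ncol(cuts))) {
      edges <- c(0, cuts[, j], np)
      totals <- vapply(seq_len(n_bins), function(b)
        sum(n_sim[(edges[b] + 1):edges[b + 1]]), numeric(1))
      best <- min(best, max(totals) - min(totals))
    }
    best
  }
  set.seed(21)
  for (i in 1:20) {
    np <- sample(4:10, 1)
    pairs <- tibble::tibble(pair_id = paste0("p", 1:np),
                            distance = sort(runif(np, 0, 9000)),
                            n_sim = sample(0:8, np, replace = TRUE))
    n_bins <- sample(2:3, 1)
    if (sum(pairs$n_sim) < n_bins) next
    b <- bin_pairs_equal_events(pairs, n_bins)
    totals <- tapply(b$n_sim, b$bin, sum)
    if (length(totals) < n_bins) next
    # greedy imbalance within one pair's worth of the exhaustive optimum
    expect_lte(max(totals) - min(totals),
               best_imbalance(pairs$n_sim, n_bins) + max(pairs$n_sim))
    # bins are contiguous in distance
    expect_true(all(diff(b$bin) >= 0))
  }
})

sim_fiber_pairs <- function(n_pairs, n_fibers, or, p_a = 0.2, p_b = 0.3,
                            distances = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(distances)) distances <- runif(n_pairs, 100, 9900)
  dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    d <- simulate_pair_features(n_fibers, p_a, p_b, or)
    tibble::tibble(pair_id = paste0("p", i), distance = distances[i],
                   fiber_id = paste0("f", seq_len(n_fibers)),
                   a = d$a, b = d$b, acc_a = TRUE, acc_b = TRUE)
  }))
}

test_that("global coordination recovers planted odds ratios", {
  for (or in c(0.3, 1, 3)) {
    fp <- sim_fiber_pairs(12, 400, or, seed = round(100 * or))
    res <- global_coordination(fp, n_bins = 2)
    for (r in seq_len(nrow(res))) {
      k <- c(res$n11[r], res$n10[r], res$n01[r], res$n00[r])
      se <- sqrt(sum(1 / pmax(k, 0.5)))
      ci <- exp(log(res$odds_ratio[r]) + c(-3, 3) * se)
      expect_true(ci[1] <= or && or <= ci[2],
                  info = sprintf("or=%g bin=%d", or, r))
    }
  }
})

test_that("shuffling features across fibers destroys coordination", {
  fp <- sim_fiber_pairs(12, 400, 3, seed = 5)
  set.seed(6)
  fp$b <- sample(fp$b)
  res <- global_coordination(fp, n_bins = 2)
  for (r in seq_len(nrow(res))) {
    k <- c(res$n11[r], res$n10[r], res$n01[r], res$n00[r])
    se <- sqrt(sum(1 / pmax(k, 0.5)))
    ci <- exp(log(res$odds_ratio[r]) + c(-3, 3) * se)
    expect_true(ci[1] <= 1 && 1 <= ci[2])
  }
})

test_that("per-locus coordination applies the OR > 1 and p < 0.05 rule", {
  strong <- tibble::tibble(pair_id = "s", distance = 500,
                           a = rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 2, 2, 20)),
                           b = rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 2, 2, 20)))
  flat <- tibble::tibble(pair_id = "f", distance = 2500,
                         a = c(TRUE, TRUE, FALSE, FALSE),
                         b = c(TRUE, FALSE, TRUE, FALSE))
  anti <- tibble::tibble(pair_id = "a", distance = 700,
                         a = rep(c(TRUE, TRUE, FALSE, FALSE), c(1, 15, 15, 1)),
                         b = rep(c(TRUE, FALSE, TRUE, FALSE), c(1, 15, 15, 1)))
  res <- per_locus_coordination(dplyr::bind_rows(strong, flat, anti))
  pp <- res$per_pair
  expect_true(pp$significant[pp$pair_id == "s"])
  expect_false(pp$significant[pp$pair_id == "f"])
  # anti-coordinated: small p but OR < 1 does not count as coordinated
  expect_lt(pp$p_value[pp$pair_id == "a"], 0.05)
  expect_false(pp$significant[pp$pair_id == "a"])
  expect_equal(res$per_bin$frac_significant[1], 0.5)  # bin [0, 2000]: s and a
})

test_that("steric exclusion shows as OR < 1 only in close peak-distance bins", {
  set.seed(14)
  reads <- list(); dists <- list()
  for (g in 1:30) {
    close <- g <= 15
    n <- 120
    if (close) {
      # mutual exclusion: PPP and PIC never on the same read
      ppp <- runif(n) < 0.3
      pic <- !ppp & runif(n) < 0.3 / 0.7
    } else {
      ppp <- runif(n) < 0.3
      pic <- runif(n) < 0.3
    }
    reads[[g]] <- tibble::tibble(gene_id = paste0("g", g),
                                 has_ppp = ppp, has_pic = pic)
    dists[[g]] <- tibble::tibble(gene_id = paste0("g", g),
                                 peak_distance = if (close) runif(1, 20, 45)
                                 else runif(1, 80, 150))
  }
  res <- pause_initiation_interference(dplyr::bind_rows(reads),
                                       dplyr::bind_rows(dists),
                                       breaks = c(0, 60, 200))
  close_row <- res[1, ]  # rows follow the cut() level order
  far_row <- res[2, ]
  expect_lt(close_row$odds_ratio, 0.5)
  expect_lt(close_row$p_value, 1e-6)
  expect_gt(far_row$odds_ratio, 0.7)
  expect_lt(far_row$odds_ratio, 1.4)
  # genes lacking either footprint type anywhere are excluded
  solo <- tibble::tibble(gene_id = "solo", has_ppp = rep(TRUE, 50),
                         has_pic = FALSE)
  res2 <- pause_initiation_interference(
    dplyr::bind_rows(dplyr::bind_rows(reads), solo),
    dplyr::bind_rows(dplyr::bind_rows(dists),
                     tibble::tibble(gene_id = "solo", peak_distance = 30)),
    breaks = c(0, 60, 200))
  expect_equal(res2$n11 + res2$n10 + res2$n01 + res2$n00,
               res$n11 + res$n10 + res$n01 + res$n00)
})

test_that("distance-matched comparison is deterministic and calibrated", {
  set.seed(8)
  mk_group <- function(group, or, n_pairs) {
    d <- simulate_pair_features(400 * n_pairs, 0.2, 0.3, or)
    idx <- rep(seq_len(n_pairs), each = 400)
    dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
      di <- d[idx == i, ]
      tibble::tibble(group = group, distance = runif(1, 100, 5000),
                     n11 = sum(di$a & di$b), n10 = sum(di$a & !di$b),
                     n01 = sum(!di$a & di$b), n00 = sum(!di$a & !di$b))
    }))
  }
  g1 <- mk_group(1, 3, 10)
  # identical groups: the difference distribution covers zero
  same <- dplyr::bind_rows(g1, dplyr::mutate(g1, group = 2))
  res <- distance_matched_comparison(same, n_iter = 300, seed = 4)
  expect_gt(res$p_difference, 0.9)
  res_b <- distance_matched_comparison(same, n_iter = 300, seed = 4)
  expect_identical(res$iterations, res_b$iterations)
  # planted separation: within-group OR 3 vs cross-group OR 1
  both <- dplyr::bind_rows(g1, mk_group(2, 1, 10))
  res2 <- distance_matched_comparison(both, n_iter = 300, seed = 4)
  s <- res2$summary
  expect_gt(s$ci_lo[s$group == 1], s$ci_hi[s$group == 2])
  expect_lt(res2$p_difference, 0.02)
  # disjoint distance support is an error
  far <- dplyr::mutate(g1, group = 2, distance = distance + 1e6)
  expect_error(distance_matched_comparison(dplyr::bind_rows(g1, far)),
               "overlapping distance")
})
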