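test_that("Wilcoxon rank-sum matches the exact reference on tie-free samples", {
  x <- c(100, 105, 110); y <- c(25, 30, 35)
  got <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-12)
  expect_true(got$exact)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    got <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles ties and degenerate samples", {
  # identical groups: every assignment gives the same rank sum
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # large degenerate samples fall through to the normal branch without NaN
  p <- wilcoxon_rank_sum(rep(1, 60), rep(1, 60))$p_value
  expect_equal(p, 1)
  # strongly separated large samples reject
  expect_lt(wilcoxon_rank_sum(rnorm(60, 10), rnorm(60, 0))$p_value, 1e-6)
})

test_that("GMM recovers a planted two-component mixture", {
  set.seed(42)
  x <- c(rnorm(1000, 185, 20), rnorm(1000, 370, 20))
  fit <- gmm_fit(x, 2, seed = 1)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_lt(abs(fit$components$mean[1] - 185), 5)
  expect_lt(abs(fit$components$mean[2] - 370), 5)
  expect_true(all(abs(fit$components$weight - 0.5) < 0.05))
  # independent cross-check against mclust on the same data
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$components$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1)
})

test_that("GMM degenerate cases behave as documented", {
  set.seed(1)
  x <- rnorm(50, 10, 2)
  fit <- gmm_fit(x, 1)
  expect_equal(fit$components$mean, mean(x))
  expect_equal(fit$components$sd, sqrt(mean((x - mean(x))^2)))
  expect_equal(fit$components$ci_lo, mean(x) - 1.96 * fit$components$sd)
  expect_error(gmm_fit(numeric(), 1), "empty")
  expect_error(gmm_fit(rnorm(15), 2), "at least")
})

test_that("nucleosome segmentation indexes components and gates by CI", {
  set.seed(5)
  pos <- c(rnorm(400, -180, 15), rnorm(400, 60, 15), rnorm(400, 245, 15))
  seg <- segment_nucleosomes_gmm(pos, 3, seed = 2)
  expect_equal(seg$components$index, c(-1L, 1L, 2L))
  # an observation far outside every CI stays unassigned
  seg2 <- segment_nucleosomes_gmm(c(pos, 5000), 3, seed = 2)
  expect_true(is.na(seg2$assignment[length(seg2$assignment)]))
  # assigned observations lie inside their component's CI
  comp <- seg$components
  ok <- !is.na(seg$assignment)
  idx <- match(seg$assignment[ok], comp$index)
  expect_true(all(pos[ok] >= comp$ci_lo[idx] & pos[ok] <= comp$ci_hi[idx]))
})

test_that("matched subsampling balances condition and neither per gene", {
  status <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", fiber_id = paste0("a", 1:5), condition = "ppp"),
    tibble::tibble(gene_id = "g1", fiber_id = paste0("b", 1:20), condition = "neither"),
    tibble::tibble(gene_id = "g2", fiber_id = paste0("c", 1:10), condition = "neither"),
    tibble::tibble(gene_id = "g3", fiber_id = paste0("d", 1:4), condition = "pic")
  )
  sub <- subsample_matched(status, "ppp", seed = 1)
  expect_equal(sum(sub$gene_id == "g1" & sub$side == "condition"), 5)
  expect_equal(sum(sub$gene_id == "g1" & sub$side == "neither"), 5)
  expect_false("g2" %in% sub$gene_id)  # no PPP fibers -> excluded
  expect_false("g3" %in% sub$gene_id)
  expect_identical(sub, subsample_matched(status, "ppp", seed = 1))
  expect_false(identical(sub$fiber_id,
                         subsample_matched(status, "ppp", seed = 2)$fiber_id))
})

test_that("+1/-1 nucleosome identification is strand-aware", {
  gene_p <- tibble::tibble(gene_id = "gp", chrom = "chrT", tss = 10000L,
                           gene_end = 15000L, strand = "+", gene_class = "polII")
  gene_m <- tibble::tibble(gene_id = "gm", chrom = "chrT", tss = 10000L,
                           gene_end = 5000L, strand = "-", gene_class = "polII")
  fb <- fibers("f1", "chrT", 8000L, 12000L, "+",
               a_sites = list(8500L), methylated = list(TRUE))
  fp <- tibble::tibble(
    fiber_id = "f1", chrom = "chrT", strand = ".",
    start = c(10040L, 10300L, 9700L, 9500L, 10010L),
    end = c(10187L, 10447L, 9847L, 9647L, 10030L),  # last one is 20 bp
    size = c(147L, 147L, 147L, 147L, 20L), n_sites = 5L,
    mean_posterior = 0.9, label = "unknown"
  )
  f_p <- plus_minus_one(fp, fb, gene_p)
  expect_equal(f_p$plus1_start, 40L)       # nearest downstream start
  expect_equal(f_p$plus1_size, 147L)
  expect_equal(f_p$minus1_end, -153L)      # 9847 -> rel end -153
  # minus strand: upstream/downstream flip
  f_m <- plus_minus_one(fp, fb, gene_m)
  expect_equal(f_m$plus1_start, 154L)      # footprint [9700,9847) -> rel start
  expect_equal(f_m$minus1_end, -39L)       # footprint [10040,10187)
})

test_that("pause-shifted +1 distributions are detected per gene and per read", {
  set.seed(33)
  n <- 25
  features <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", fiber_id = paste0("p", 1:n), ppp = TRUE,
                   plus1_start = round(rnorm(n, 115, 15)),
                   plus1_size = round(rnorm(n, 147, 8))),
    tibble::tibble(gene_id = "g1", fiber_id = paste0("q", 1:n), ppp = FALSE,
                   plus1_start = round(rnorm(n, 45, 15)),
                   plus1_size = round(rnorm(n, 147, 8)))
  )
  res <- plus_one_stats(features, n_boot = 500, seed = 3)
  expect_lt(res$per_gene$p_distance, 0.001)
  expect_gt(res$per_gene$p_size, 0.01)
  pr <- res$per_read[res$per_read$feature == "plus1_start", ]
  expect_gt(mean(pr$outside), 0.9)  # PPP reads sit far outside the no-PPP CI
  expect_true(all(pr$value > pr$ci_hi | !pr$outside))
})

test_that("bootstrap of a constant sample has a zero-width interval", {
  features <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g", fiber_id = paste0("p", 1:3), ppp = TRUE,
                   plus1_start = c(100L, 100L, 100L), plus1_size = 147L),
    tibble::tibble(gene_id = "g", fiber_id = paste0("q", 1:3), ppp = FALSE,
                   plus1_start = 40L, plus1_size = 147L)
  )
  res <- plus_one_stats(features, n_boot = 200, seed = 1)
  pr <- res$per_read[res$per_read$feature == "plus1_start", ]
  expect_equal(unique(pr$ci_lo), 40)
  expect_equal(unique(pr$ci_hi), 40)
})

test_that("absent-nucleosome fold follows the ratio arithmetic", {
  slots <- tibble::tibble(index = 1L, ci_lo = 100, ci_hi = 200)
  mk_spans <- function(n_ppp, n_other) tibble::tibble(
    fiber_id = paste0("f", seq_len(n_ppp + n_other)),
    rel_lo = -1000, rel_hi = 1000,
    ppp = c(rep(TRUE, n_ppp), rep(FALSE, n_other)))
  # absent 20/100 (PPP) vs 10/100 (no PPP): +100%
  spans <- mk_spans(100, 100)
  present <- c(paste0("f", 21:100), paste0("f", 111:200))
  mids <- tibble::tibble(fiber_id = present, mid_rel = 150)
  res <- absent_nucleosome_fold(mids, spans, slots, n_boot = 500, seed = 2)
  expect_equal(res$fold_increase_pct, 100)
  expect_true(res$ci_lo < 100 && res$ci_hi > 100)
  # equal proportions: 0% and the CI covers 0
  present_eq <- c(paste0("f", 11:100), paste0("f", 111:200))
  mids_eq <- tibble::tibble(fiber_id = present_eq, mid_rel = 150)
  res_eq <- absent_nucleosome_fold(mids_eq, spans, slots, n_boot = 500, seed = 2)
  expect_equal(res_eq$fold_increase_pct, 0)
  expect_true(res_eq$ci_lo <= 0 && res_eq$ci_hi >= 0)
})

test_that("shifted +1 calls use the inclusive 70-150 bp window", {
  features <- tibble::tibble(
    gene_id = "g", fiber_id = paste0("f", 1:5), ppp = TRUE,
    plus1_start = c(100L, 40L, 150L, 70L, NA), plus1_size = 147L
  )
  calls <- call_shifted_plus1(features)
  expect_equal(calls$shifted, c(TRUE, FALSE, TRUE, TRUE, NA))
})

test_that("seed-repeated statistics summarize their spread", {
  res <- resample_stat(function(s) { set.seed(s); mean(rnorm(50)) }, 1:60)
  expect_equal(res$n_seeds, 60)
  expect_lt(abs(res$mean), 0.06)
  expect_true(res$q025 < res$mean && res$mean < res$q975)
})
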