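#' Fisher's exact test for a 2x2 contingency table
#'
#' The reported odds ratio is the cross-product `ad/bc`, with the
#' Haldane-Anscombe correction (+0.5 on every cell) applied when any cell is
#' zero; the two-sided p-value sums the hypergeometric probabilities of all
#' tables (at fixed margins) no more probable than the observed one,
#' computed from the uncorrected counts. The odds ratio and p-value are both
#' invariant under transposing the table.
#'
#' @param counts 2x2 non-negative integer matrix: rows = feature at element
#'   A yes/no, columns = feature at element B yes/no.
#' @return one-row tibble: n11, n10, n01, n00, n, odds_ratio, p_value.
#' @export
fisher_exact <- function(counts) {
  counts <- matrix(as.numeric(counts), 2, 2)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  n <- sum(counts)
  assert_that(n > 0, "all-zero table: test undefined")
  a <- counts[1, 1]; b <- counts[1, 2]; cc <- counts[2, 1]; d <- counts[2, 2]
  if (any(counts == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  tibble(n11 = a, n10 = b, n01 = cc, n00 = d, n = n,
         odds_ratio = or, p_value = p)
}

#' Build a single-fiber co-occupancy contingency table
#'
#' Counts fibers by the joint presence of a feature at two elements. The
#' caller supplies one row per fiber that fully spans both elements'
#' evaluation windows; when `require_accessible` is set, fibers whose
#' promoter is inaccessible (or not evaluable) at either element are
#' excluded before counting.
#'
#' @param df tibble with logical columns `a`, `b` (feature present at
#'   element A / B) and, if `require_accessible`, logical columns `acc_a`,
#'   `acc_b`.
#' @param require_accessible exclude fibers not accessible at both elements.
#' @return one-row tibble as returned by [fisher_exact()].
#' @export
build_cooccupancy_table <- function(df, require_accessible = FALSE) {
  if (require_accessible) {
    df <- filter(df, !is.na(.data$acc_a), !is.na(.data$acc_b),
                 .data$acc_a, .data$acc_b)
  }
  counts <- matrix(c(sum(df$a & df$b), sum(df$a & !df$b),
                     sum(!df$a & df$b), sum(!df$a & !df$b)),
                   2, 2, byrow = TRUE)
  fisher_exact(counts)
}

# Raw 2x2 counts without the test (for pooling).
cooccupancy_counts <- function(df, require_accessible = FALSE) {
  if (require_accessible) {
    df <- filter(df, !is.na(.data$acc_a), !is.na(.data$acc_b),
                 .data$acc_a, .data$acc_b)
  }
  c(n11 = sum(df$a & df$b), n10 = sum(df$a & !df$b),
    n01 = sum(!df$a & df$b), n00 = sum(!df$a & !df$b))
}

#' Bin element pairs for roughly equal simultaneous-event counts
#'
#' Walks pairs in distance order and closes a bin whenever its cumulative
#' simultaneous-event count reaches `total / n_bins`, yielding contiguous
#' distance bins each holding a roughly equal number of simultaneous
#' events (each bin's total can overshoot by at most the largest single
#' pair's count).
#'
#' @param pairs tibble with columns `pair_id`, `distance`, `n_sim`
#'   (simultaneous-event count per pair).
#' @param n_bins requested number of bins.
#' @param max_dist drop pairs at or beyond this distance (default 10 kb).
#' @return `pairs` (filtered, distance-sorted) with an integer `bin` column.
#' @export
bin_pairs_equal_events <- function(pairs, n_bins, max_dist = 10000) {
  pairs <- arrange(filter(pairs, .data$distance < max_dist), .data$distance)
  total <- sum(pairs$n_sim)
  if (total < n_bins) {
    warn(sprintf("only %d simultaneous events for %d requested bins; using fewer bins",
                 total, n_bins))
    n_bins <- max(1L, total)
  }
  target <- total / n_bins
  bin <- integer(nrow(pairs))
  cur <- 1L; acc <- 0
  for (i in seq_len(nrow(pairs))) {
    bin[i] <- cur
    acc <- acc + pairs$n_sim[i]
    if (acc >= target && cur < n_bins) { cur <- cur + 1L; acc <- 0 }
  }
  pairs$bin <- bin
  pairs
}

#' Global coordination across binned element pairs
#'
#' Pools single-fiber co-occupancy tables within distance bins built by
#' [bin_pairs_equal_events()] and applies [fisher_exact()] per bin: the
#' distance-resolved co-occupancy odds ratio.
#'
#' @param fiber_pairs tibble with one row per (fiber, pair): columns
#'   `pair_id`, `distance`, logical `a`, `b`, and optionally `acc_a`,
#'   `acc_b`.
#' @param n_bins number of distance bins.
#' @param max_dist maximum TSS-to-TSS distance (default 10 kb).
#' @param require_accessible only count fibers accessible at both elements.
#' @return tibble per bin: bin, d_lo, d_hi, n_pairs, n11..n00, odds_ratio,
#'   p_value.
#' @export
global_coordination <- function(fiber_pairs, n_bins = 6, max_dist = 10000,
                                require_accessible = FALSE) {
  per_pair <- fiber_pairs |>
    group_by(.data$pair_id, .data$distance) |>
    summarise(n_sim = sum(.data$a & .data$b), .groups = "drop") |>
    rename(distance = "distance")
  binned <- bin_pairs_equal_events(
    tibble(pair_id = per_pair$pair_id, distance = per_pair$distance,
           n_sim = per_pair$n_sim),
    n_bins, max_dist
  )
  out <- map(sort(unique(binned$bin)), function(b) {
    ids <- binned$pair_id[binned$bin == b]
    df <- filter(fiber_pairs, .data$pair_id %in% ids)
    k <- cooccupancy_counts(df, require_accessible)
    if (sum(k) == 0) {
      warn(sprintf("distance bin %d is empty; skipped", b))
      return(NULL)
    }
    res <- fisher_exact(matrix(k, 2, 2, byrow = TRUE))
    mutate(res, bin = b,
           d_lo = min(binned$distance[binned$bin == b]),
           d_hi = max(binned$distance[binned$bin == b]),
           n_pairs = length(ids), .before = 1)
  })
  bind_rows(out)
}

#' Per-locus coordination
#'
#' Tests each element pair separately: a pair is significantly coordinated
#' when its Fisher odds ratio exceeds 1 and p < 0.05. Reports the fraction
#' of significant pairs per distance bin.
#'
#' @inheritParams global_coordination
#' @param breaks distance bin edges (default 2 kb bins to 10 kb).
#' @return list: `per_pair` (pair_id, distance, odds_ratio, p_value,
#'   significant), `per_bin` (distance bin, n_pairs, frac_significant).
#' @export
per_locus_coordination <- function(fiber_pairs, breaks = seq(0, 10000, 2000),
                                   require_accessible = FALSE) {
  per_pair <- map(unique(fiber_pairs$pair_id), function(id) {
    df <- filter(fiber_pairs, .data$pair_id == id)
    k <- cooccupancy_counts(df, require_accessible)
    if (sum(k) == 0) return(NULL)
    res <- fisher_exact(matrix(k, 2, 2, byrow = TRUE))
    tibble(pair_id = id, distance = df$distance[1],
           odds_ratio = res$odds_ratio, p_value = res$p_value,
           significant = res$odds_ratio > 1 & res$p_value < 0.05)
  })
  per_pair <- bind_rows(per_pair)
  per_bin <- per_pair |>
    mutate(bin = cut(.data$distance, breaks, include.lowest = TRUE)) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$bin) |>
    summarise(n_pairs = n(), frac_significant = mean(.data$significant),
              .groups = "drop")
  list(per_pair = per_pair, per_bin = per_bin)
}

#' Pause-inhibited initiation across peak-distance bins
#'
#' Restricted to genes carrying at least one PPP and at least one PIC
#' footprint somewhere among their fibers, bins genes by the distance
#' between their primary CAGE-seq and PRO-seq peaks, pools per-bin 2x2
#' tables of (PPP on read) x (PIC on read), and tests each bin with
#' [fisher_exact()]. An odds ratio below 1 in close-peaked bins is the
#' signature of steric competition between the paused polymerase and the
#' preinitiation complex.
#'
#' @param reads tibble: gene_id, has_ppp, has_pic (one row per read).
#' @param peak_distance tibble: gene_id, peak_distance (bp between primary
#'   CAGE and PRO peaks).
#' @param breaks peak-distance bin edges.
#' @return tibble per bin: bin label, n_genes, n11..n00, odds_ratio,
#'   p_value; bins with no events are skipped.
#' @export
pause_initiation_interference <- function(reads, peak_distance,
                                          breaks = c(0, 45, 60, 75, 200)) {
  keep <- reads |>
    group_by(.data$gene_id) |>
    summarise(any_ppp = any(.data$has_ppp), any_pic = any(.data$has_pic),
              .groups = "drop") |>
    filter(.data$any_ppp, .data$any_pic)
  reads <- filter(reads, .data$gene_id %in% keep$gene_id)
  reads <- left_join(reads, peak_distance, by = "gene_id")
  reads <- mutate(reads, bin = cut(.data$peak_distance, breaks,
                                   include.lowest = TRUE))
  out <- map(levels(droplevels(reads$bin)), function(b) {
    df <- filter(reads, .data$bin == b)
    if (nrow(df) == 0 || sum(df$has_ppp & df$has_pic) + sum(df$has_ppp) +
          sum(df$has_pic) == 0) {
      warn(sprintf("peak-distance bin %s has no events; skipped", b))
      return(NULL)
    }
    k <- matrix(c(sum(df$has_ppp & df$has_pic), sum(df$has_ppp & !df$has_pic),
                  sum(!df$has_ppp & df$has_pic), sum(!df$has_ppp & !df$has_pic)),
                2, 2, byrow = TRUE)
    res <- fisher_exact(k)
    mutate(res, bin = b, n_genes = length(unique(df$gene_id)), .before = 1)
  })
  bind_rows(out)
}

#' Distance-matched comparison of co-occupancy between two pair groups
#'
#' Compares pooled co-occupancy odds ratios between two groups of element
#' pairs (e.g. pairs within one TAD versus pairs separated by a TAD
#' boundary or insulator peak) while controlling for the distance
#' confound: in each of `n_iter` iterations, pairs are sampled from both
#' groups to a common distance histogram (shared bins of `bin_width` bp,
#' per-bin count = the smaller group's count), each group's sampled tables
#' are pooled into one odds ratio, and the iteration distribution yields
#' means, percentile confidence intervals, and a two-sided p-value for the
#' group difference.
#'
#' @param pairs tibble with one row per pair: `group` (1 or 2), `distance`,
#'   and contingency counts `n11`, `n10`, `n01`, `n00`.
#' @param n_iter sampling iterations (default 10000).
#' @param bin_width distance histogram bin width in bp (default 250).
#' @param seed integer seed.
#' @return list: `summary` (per group: mean OR, ci_lo, ci_hi), `p_difference`
#'   (two-sided), `iterations` (tibble of per-iteration or1, or2).
#' @export
distance_matched_comparison <- function(pairs, n_iter = 10000, bin_width = 250,
                                        seed = 1L) {
  pairs <- mutate(pairs, dbin = floor(.data$distance / bin_width))
  shared <- intersect(pairs$dbin[pairs$group == 1], pairs$dbin[pairs$group == 2])
  assert_that(length(shared) > 0,
              "no overlapping distance support between the two groups")
  pooled_or <- function(df) {
    a <- sum(df$n11); b <- sum(df$n10); cc <- sum(df$n01); d <- sum(df$n00)
    if (any(c(a, b, cc, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
  }
  with_seed(seed, {
    or1 <- numeric(n_iter); or2 <- numeric(n_iter)
    g1 <- filter(pairs, .data$group == 1, .data$dbin %in% shared)
    g2 <- filter(pairs, .data$group == 2, .data$dbin %in% shared)
    for (it in seq_len(n_iter)) {
      take <- function(g) {
        idx <- unlist(lapply(shared, function(b) {
          rows <- which(g$dbin == b)
          m <- min(sum(g1$dbin == b), sum(g2$dbin == b))
          if (m == 0) return(integer())
          rows[sample.int(length(rows), m)]
        }))
        g[idx, ]
      }
      or1[it] <- pooled_or(take(g1))
      or2[it] <- pooled_or(take(g2))
    }
    d <- or1 - or2
    list(
      summary = tibble(
        group = c(1L, 2L),
        mean_or = c(mean(or1), mean(or2)),
        ci_lo = c(quantile(or1, 0.025, names = FALSE),
                  quantile(or2, 0.025, names = FALSE)),
        ci_hi = c(quantile(or1, 0.975, names = FALSE),
                  quantile(or2, 0.975, names = FALSE))
      ),
      p_difference = min(1, 2 * min(mean(d <= 0), mean(d >= 0))),
      iterations = tibble(or1 = or1, or2 = or2)
    )
  })
}
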