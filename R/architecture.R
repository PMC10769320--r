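#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when the enumeration of all `choose(n+m, n)` group assignments is
#' small enough (covers `min(n, m) <= 8` for balanced groups and handles
#' ties and degenerate samples: identical groups give p = 1); otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param max_enum largest enumeration size for the exact branch.
#' @return one-row tibble: statistic (rank sum of `x`), p_value, exact.
#' @export
wilcoxon_rank_sum <- function(x, y, max_enum = 40000) {
  n <- length(x); m <- length(y); N <- n + m
  assert_that(n >= 1 && m >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (choose(N, min(n, m)) <= max_enum) {
    idx <- utils::combn(N, n)
    Ts <- colSums(matrix(r[idx], nrow = n))
    p <- mean(abs(Ts - mu) >= abs(W - mu) - 1e-9)
    return(tibble(statistic = W, p_value = p, exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(tibble(statistic = W, p_value = 1, exact = FALSE))
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  tibble(statistic = W, p_value = min(1, 2 * pnorm(-max(z, 0))), exact = FALSE)
}

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Used to segment TSS-relative nucleosome footprint positions into
#' positional classes. Initialized from a seeded k-means partition; the EM
#' log-likelihood trace is retained (it is non-decreasing, a property the
#' test suite checks). Component standard deviations are floored at 1e-3 bp
#' to prevent degenerate collapse.
#'
#' @param x numeric observations.
#' @param k number of components (>= 1); requires at least `10 k` points.
#' @param seed integer seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule; non-convergence after `max_iter`
#'   iterations is an error carrying diagnostics.
#' @return object of class `gmm_fit`: components tibble (mean, sd, weight,
#'   ci_lo, ci_hi = mean +/- 1.96 sd), loglik_trace, responsibilities.
#' @export
gmm_fit <- function(x, k, seed = 1L, max_iter = 500L, tol = 1e-8) {
  assert_that(length(x) > 0, "empty input")
  assert_that(k >= 1, "k must be >= 1")
  assert_that(length(x) >= 10 * k,
              sprintf("need at least %d observations for k = %d", 10 * k, k))
  if (k == 1) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    comp <- tibble(mean = mu, sd = s, weight = 1,
                   ci_lo = mu - 1.96 * s, ci_hi = mu + 1.96 * s)
    return(structure(list(components = comp,
                          loglik_trace = sum(dnorm(x, mu, s, log = TRUE)),
                          resp = matrix(1, length(x), 1), k = 1L),
                     class = "gmm_fit"))
  }
  with_seed(seed, {
    km <- kmeans(x, centers = k, nstart = 5)
    mu <- as.numeric(km$centers)
    s <- vapply(seq_len(k), function(j) {
      xs <- x[km$cluster == j]
      max(sqrt(mean((xs - mu[j])^2)), 1e-3)
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(x)
    trace <- numeric(0)
    resp <- NULL
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                     numeric(length(x)))
      dens <- matrix(dens, ncol = k)
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      trace <- c(trace, sum(log(tot)))
      resp <- dens / tot
      nk <- colSums(resp)
      w <- nk / length(x)
      mu <- colSums(resp * x) / nk
      s <- pmax(sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk), 1e-3)
      if (it > 1 && trace[it] - trace[it - 1] < tol) {
        comp <- tibble(mean = mu, sd = s, weight = w,
                       ci_lo = mu - 1.96 * s, ci_hi = mu + 1.96 * s)
        o <- order(comp$mean)
        return(structure(list(components = comp[o, ], loglik_trace = trace,
                              resp = resp[, o, drop = FALSE], k = as.integer(k)),
                         class = "gmm_fit"))
      }
    }
    abort(sprintf(paste0("GMM EM did not converge after %d iterations ",
                         "(last loglik %.6g, gain %.3g)"),
                  max_iter, trace[max_iter], trace[max_iter] - trace[max_iter - 1]))
  })
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit>", x$k, "component(s)\n")
  print(as.data.frame(round(x$components, 2)))
  invisible(x)
}

#' @rdname gmm_fit
#' @param x a `gmm_fit`.
#' @param ... unused.
#' @export
tidy.gmm_fit <- function(x, ...) x$components

#' @rdname gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik_trace[length(x$loglik_trace)],
         n_iter = length(x$loglik_trace), n = nrow(x$resp))
}

#' Segment nucleosome positions with a Gaussian mixture
#'
#' Fits a `k`-component 1-D GMM to TSS-relative nucleosome footprint
#' positions, ranks components by mean into signed indices (-m..-1 for
#' negative means, +1..+p for non-negative, counting outward from the TSS),
#' and assigns each footprint to a component only when it falls inside that
#' component's 95% confidence interval (mean +/- 1.96 sd); footprints
#' outside every interval stay unassigned.
#'
#' @param positions numeric TSS-relative positions (footprint starts by
#'   default in the calling analyses).
#' @param k number of components.
#' @param seed integer seed.
#' @return list: `components` (tibble with signed index, mean, sd, weight,
#'   ci_lo, ci_hi), `assignment` (integer index per position, `NA` if
#'   unassigned), `fit` (the underlying [gmm_fit()]).
#' @export
segment_nucleosomes_gmm <- function(positions, k, seed = 1L) {
  fit <- gmm_fit(positions, k, seed = seed)
  comp <- fit$components
  neg <- which(comp$mean < 0); pos <- which(comp$mean >= 0)
  comp$index <- NA_integer_
  comp$index[neg] <- -rev(seq_along(neg))   # most negative = -m
  comp$index[pos] <- seq_along(pos)
  # assign by max responsibility, gated by the 95% CI
  best <- max.col(fit$resp)
  inside <- positions >= comp$ci_lo[best] & positions <= comp$ci_hi[best]
  assignment <- ifelse(inside, comp$index[best], NA_integer_)
  list(components = select(comp, "index", "mean", "sd", "weight",
                           "ci_lo", "ci_hi"),
       assignment = assignment, fit = fit)
}

#' Matched subsampling of fibers by footprint condition
#'
#' At each gene, fibers (pre-filtered to accessible promoters) are split
#' into condition-positive (carrying a PPP or PIC footprint) and neither
#' (carrying neither); equal counts are drawn from both sides so downstream
#' comparisons are balanced per gene. Genes lacking either side are
#' excluded.
#'
#' @param status tibble: gene_id, fiber_id, condition (`"ppp"`, `"pic"` or
#'   `"neither"`).
#' @param condition `"ppp"` or `"pic"`.
#' @param seed integer seed.
#' @return tibble: gene_id, fiber_id, side (`"condition"` or `"neither"`).
#' @export
subsample_matched <- function(status, condition = c("ppp", "pic"), seed) {
  condition <- match.arg(condition)
  with_seed(seed, {
    out <- status |>
      group_by(.data$gene_id) |>
      dplyr::group_map(function(df, key) {
        pos <- df$fiber_id[df$condition == condition]
        neg <- df$fiber_id[df$condition == "neither"]
        m <- min(length(pos), length(neg))
        if (m == 0) return(NULL)
        tibble(gene_id = key$gene_id,
               fiber_id = c(sample(pos, m), sample(neg, m)),
               side = rep(c("condition", "neither"), each = m))
      })
    bind_rows(out)
  })
}

#' Repeat a sampled statistic over many seeds
#'
#' Runs `stat_fn(seed)` across the given seeds (at least 50 recommended for
#' sampling-based analyses) and summarizes the spread.
#'
#' @param stat_fn function of a single integer seed returning one number.
#' @param seeds integer vector of seeds.
#' @return one-row tibble: mean, sd, q025, q975, n_seeds.
#' @export
resample_stat <- function(stat_fn, seeds = 1:50) {
  v <- vapply(seeds, stat_fn, numeric(1))
  tibble(mean = mean(v), sd = sd(v),
         q025 = quantile(v, 0.025, names = FALSE),
         q975 = quantile(v, 0.975, names = FALSE), n_seeds = length(seeds))
}

# TSS-relative footprint edges: returns fp with rel_start/rel_end such that
# the footprint covers [rel_start, rel_end) in TSS-relative coordinates.
fp_relative <- function(fp, gene) {
  if (gene$strand == "+") {
    mutate(fp, rel_start = .data$start - gene$tss, rel_end = .data$end - gene$tss)
  } else {
    mutate(fp, rel_start = gene$tss - .data$end + 1L,
           rel_end = gene$tss - .data$start + 1L)
  }
}

#' Per-fiber +1 and -1 nucleosome features at a gene
#'
#' The +1 nucleosome of a fiber is its first single-nucleosome footprint
#' (90-200 bp) starting at or downstream of the TSS; the -1 nucleosome is
#' the last one ending at or upstream of it. Positions are strand-aware and
#' TSS-relative.
#'
#' @param fp footprint tibble.
#' @param fb fiber tibble.
#' @param gene one-row annotation tibble.
#' @param rules rule constants.
#' @return tibble: fiber_id, plus1_start, plus1_size, minus1_end,
#'   minus1_size (NA where the nucleosome is absent).
#' @export
plus_minus_one <- function(fp, fb, gene, rules = classification_rules()) {
  fpc <- fp[fp$chrom == gene$chrom, ]
  fpc <- fpc[is_single_nucleosome(fpc$end - fpc$start, rules), ]
  fpc <- fp_relative(fpc, gene)
  out <- map(seq_len(nrow(fb)), function(i) {
    f <- fpc[fpc$fiber_id == fb$fiber_id[i], ]
    down <- f[f$rel_start >= 0, ]
    up <- f[f$rel_end <= 0, ]
    p1 <- if (nrow(down) > 0) down[which.min(down$rel_start), ] else NULL
    m1 <- if (nrow(up) > 0) up[which.max(up$rel_end), ] else NULL
    tibble(
      fiber_id = fb$fiber_id[i],
      plus1_start = if (is.null(p1)) NA_integer_ else p1$rel_start,
      plus1_size = if (is.null(p1)) NA_integer_ else p1$end - p1$start,
      minus1_end = if (is.null(m1)) NA_integer_ else m1$rel_end,
      minus1_size = if (is.null(m1)) NA_integer_ else m1$end - m1$start
    )
  })
  bind_rows(out)
}

#' Pause-associated +1 nucleosome statistics
#'
#' Per gene: two-sided Wilcoxon rank-sum tests comparing the +1 nucleosome
#' distance (TSS-relative start) and size between fibers with and without a
#' PPP footprint. Per read: the no-PPP fibers' feature distribution is
#' bootstrap-resampled to a mean and 95% percentile confidence interval,
#' and each PPP fiber is flagged when its feature falls outside that
#' interval. Genes with fewer than two fibers on either side are skipped.
#'
#' @param features tibble from [plus_minus_one()] with an added logical
#'   column `ppp` and a `gene_id` column.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list: `per_gene` (gene_id, n_ppp, n_other, p_distance, p_size),
#'   `per_read` (gene_id, fiber_id, feature, value, boot_mean, ci_lo,
#'   ci_hi, outside).
#' @export
plus_one_stats <- function(features, n_boot = 1000, seed = 1L) {
  feats <- filter(features, !is.na(.data$plus1_start))
  per_gene <- list(); per_read <- list()
  with_seed(seed, {
    for (g in unique(feats$gene_id)) {
      df <- feats[feats$gene_id == g, ]
      a <- df[df$ppp, ]; b <- df[!df$ppp, ]
      if (nrow(a) < 2 || nrow(b) < 2) next
      per_gene[[g]] <- tibble(
        gene_id = g, n_ppp = nrow(a), n_other = nrow(b),
        p_distance = wilcoxon_rank_sum(a$plus1_start, b$plus1_start)$p_value,
        p_size = wilcoxon_rank_sum(a$plus1_size, b$plus1_size)$p_value
      )
      for (feat in c("plus1_start", "plus1_size")) {
        base <- b[[feat]]
        bm <- vapply(seq_len(n_boot), function(i)
          mean(sample(base, length(base), replace = TRUE)), numeric(1))
        ci <- quantile(bm, c(0.025, 0.975), names = FALSE)
        per_read[[paste(g, feat)]] <- tibble(
          gene_id = g, fiber_id = a$fiber_id, feature = feat,
          value = as.numeric(a[[feat]]), boot_mean = mean(bm),
          ci_lo = ci[1], ci_hi = ci[2],
          outside = a[[feat]] < ci[1] | a[[feat]] > ci[2]
        )
      }
    }
  })
  list(per_gene = bind_rows(per_gene), per_read = bind_rows(per_read))
}

#' Fold-increase of absent nucleosomes at positioned slots
#'
#' For each nucleosome slot (a GMM component's 95% interval in TSS-relative
#' coordinates), a fiber spanning the slot counts as "absent" when no
#' nucleosome footprint midpoint falls inside the interval. Reports the
#' percentage fold-increase of absence in PPP fibers over no-PPP fibers,
#' `(p_absent(PPP) / p_absent(noPPP) - 1) * 100`, with a bootstrap
#' percentile confidence interval over fibers.
#'
#' @param nuc_mids tibble: fiber_id, mid_rel (TSS-relative nucleosome
#'   footprint midpoints).
#' @param spans tibble: fiber_id, rel_lo, rel_hi (fiber span in TSS-relative
#'   coordinates), ppp (logical).
#' @param slots tibble: index, ci_lo, ci_hi (from
#'   [segment_nucleosomes_gmm()]).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return tibble per slot: index, p_absent_ppp, p_absent_other,
#'   fold_increase_pct (NA and flagged when the no-PPP absence rate is 0),
#'   ci_lo, ci_hi, n_ppp, n_other.
#' @export
absent_nucleosome_fold <- function(nuc_mids, spans, slots, n_boot = 1000,
                                   seed = 1L) {
  with_seed(seed, {
    out <- map(seq_len(nrow(slots)), function(s) {
      lo <- slots$ci_lo[s]; hi <- slots$ci_hi[s]
      sp <- spans[spans$rel_lo <= lo & spans$rel_hi >= hi, ]
      present_ids <- unique(nuc_mids$fiber_id[nuc_mids$mid_rel >= lo &
                                                nuc_mids$mid_rel <= hi])
      sp$absent <- !(sp$fiber_id %in% present_ids)
      a <- sp$absent[sp$ppp]; b <- sp$absent[!sp$ppp]
      pa <- mean(a); pb <- mean(b)
      fold <- function(x, y) {
        py <- mean(y)
        if (is.nan(py) || py == 0) NA_real_ else (mean(x) / py - 1) * 100
      }
      est <- fold(a, b)
      if (is.na(est)) warn(sprintf("slot %d: no-PPP absence rate is 0 or empty; fold undefined",
                                   slots$index[s]))
      boots <- vapply(seq_len(n_boot), function(i)
        fold(sample(a, length(a), replace = TRUE),
             sample(b, length(b), replace = TRUE)), numeric(1))
      ci <- quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
      tibble(index = slots$index[s], p_absent_ppp = pa, p_absent_other = pb,
             fold_increase_pct = est, ci_lo = ci[1], ci_hi = ci[2],
             n_ppp = length(a), n_other = length(b))
    })
    bind_rows(out)
  })
}

#' Call shifted +1 nucleosomes
#'
#' A fiber's +1 nucleosome is shifted when it starts between 70 and 150 bp
#' downstream of the TSS (inclusive). Fibers without an identifiable +1
#' nucleosome are not evaluable (`NA`).
#'
#' @param features tibble from [plus_minus_one()].
#' @return `features` with a logical `shifted` column added.
#' @export
call_shifted_plus1 <- function(features) {
  mutate(features,
         shifted = ifelse(is.na(.data$plus1_start), NA,
                          .data$plus1_start >= 70 & .data$plus1_start <= 150))
}
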