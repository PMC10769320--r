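# Genomic half-open interval covering TSS-relative positions [a, b).
rel_window <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b + 1L, tss - a + 1L)
}

#' Call TSS-proximal signal peaks
#'
#' Scans a sliding 20 bp window over the assay-specific TSS-relative range
#' (CAGE-seq and START-seq: -50 to +50 bp; PRO-seq: 0 to +100 bp). Each
#' window position contributes its per-base maximum as a candidate peak
#' (ties resolved toward the position closest to the TSS); candidates below
#' the 10-read floor are dropped; the strongest survivor is the primary
#' peak. Secondary peaks must have at most one tenth of the primary's
#' coverage; stronger non-primary candidates are discarded by default, or —
#' with `strict_primary = TRUE` — flag the gene for exclusion. For CAGE the
#' primary peak position becomes the adjusted TSS.
#'
#' @param track signal track tibble.
#' @param genes annotation tibble (see [read_gene_bed()]).
#' @param assay `"PRO"`, `"CAGE"` or `"START"`.
#' @param window_size sliding window width in bp (default 20).
#' @param min_reads primary/candidate peak floor (default 10 reads).
#' @param strict_primary when `TRUE`, a non-primary candidate with more than
#'   primary/10 coverage marks the gene (`strict_violation`) instead of
#'   being silently discarded.
#' @return tibble with one row per gene: gene_id, assay, primary_peak
#'   (genomic bp or NA), primary_value, secondary_peaks (list column),
#'   adjusted_tss, strict_violation.
#' @export
call_tss_peaks <- function(track, genes, assay = c("PRO", "CAGE", "START"),
                           window_size = 20L, min_reads = 10,
                           strict_primary = FALSE) {
  assay <- match.arg(assay)
  rng <- if (assay == "PRO") c(0L, 100L) else c(-50L, 50L)
  out <- map(seq_len(nrow(genes)), function(g) {
    tss <- genes$tss[g]; strand <- genes$strand[g]
    rel <- seq.int(rng[1], rng[2])
    gen <- tss_absolute(rel, tss, strand)
    keep <- gen >= 0
    if (!all(keep)) {
      warn(sprintf("gene '%s': scan window clipped at contig start", genes$gene_id[g]))
      rel <- rel[keep]; gen <- gen[keep]
    }
    v <- vapply(gen, function(p)
      sum(track$score[track$chrom == genes$chrom[g] & track$pos == p]),
      numeric(1))
    cand <- integer(0)
    n <- length(rel)
    if (n >= 1) {
      w <- min(window_size, n)
      for (s in seq_len(n - w + 1L)) {
        win <- s:(s + w - 1L)
        mx <- max(v[win])
        if (mx <= 0) next
        at <- win[v[win] == mx]
        at <- at[order(abs(rel[at]), rel[at])][1]  # tie: closest to TSS
        cand <- c(cand, at)
      }
    }
    cand <- unique(cand)
    cand <- cand[v[cand] >= min_reads]
    if (length(cand) == 0) {
      return(tibble(gene_id = genes$gene_id[g], assay = assay,
                    primary_peak = NA_integer_, primary_value = NA_real_,
                    secondary_peaks = list(integer()),
                    adjusted_tss = tss, strict_violation = FALSE))
    }
    ord <- order(-v[cand], abs(rel[cand]), rel[cand])
    cand <- cand[ord]
    primary <- cand[1]
    others <- cand[-1]
    violating <- others[v[others] > v[primary] / 10]
    secondary <- setdiff(others, violating)
    tibble(
      gene_id = genes$gene_id[g], assay = assay,
      primary_peak = as.integer(gen[primary]), primary_value = v[primary],
      secondary_peaks = list(as.integer(gen[secondary])),
      adjusted_tss = if (assay == "CAGE") as.integer(gen[primary]) else tss,
      strict_violation = strict_primary && length(violating) > 0
    )
  })
  bind_rows(out)
}

#' Pause index per gene
#'
#' Ratio of PRO-seq coverage density in the promoter region (-100 to +300 bp
#' relative to the TSS, a 400 bp window) to density in the gene body (+300 bp
#' after the TSS to the gene end), both normalized per bp, making the index
#' unit-free. Genes whose body has zero coverage get `NA` (excluded from
#' binning). Bins follow the convention high: PI >= 100; mid: 100 > PI >= 10;
#' low: PI < 10.
#'
#' @param track PRO-seq signal track.
#' @param genes annotation tibble.
#' @return tibble: gene_id, promoter_density, body_density, pause_index,
#'   pause_bin.
#' @export
pause_index <- function(track, genes) {
  out <- map(seq_len(nrow(genes)), function(g) {
    tss <- genes$tss[g]; strand <- genes$strand[g]
    glen <- abs(genes$gene_end[g] - tss)
    assert_that(glen > 300, sprintf("gene '%s': body length must be > 0 (gene span > 300 bp)",
                                    genes$gene_id[g]))
    pw <- rel_window(tss, strand, -100L, 300L)
    bw <- rel_window(tss, strand, 300L, glen)
    prom <- track_sum(track, genes$chrom[g], pw[1], pw[2]) / 400
    body_len <- glen - 300
    body <- track_sum(track, genes$chrom[g], bw[1], bw[2]) / body_len
    pi_val <- if (body == 0) NA_real_ else prom / body
    tibble(gene_id = genes$gene_id[g], promoter_density = prom,
           body_density = body, pause_index = pi_val,
           pause_bin = pause_bin(pi_val))
  })
  bind_rows(out)
}

#' Pause-index bin
#'
#' @param pi_val pause index value(s).
#' @return `"high"` (PI >= 100), `"mid"` (100 > PI >= 10), `"low"` (PI < 10),
#'   or `NA` for undefined PI.
#' @export
pause_bin <- function(pi_val) {
  dplyr::case_when(
    is.na(pi_val) ~ NA_character_,
    pi_val >= 100 ~ "high",
    pi_val >= 10 ~ "mid",
    TRUE ~ "low"
  )
}

#' Expression level per gene
#'
#' PRO-seq coverage in the gene body (+300 bp after the TSS to the gene end)
#' normalized by body length.
#'
#' @param track PRO-seq signal track.
#' @param genes annotation tibble.
#' @return tibble: gene_id, expression.
#' @export
expression_level <- function(track, genes) {
  out <- map(seq_len(nrow(genes)), function(g) {
    tss <- genes$tss[g]; glen <- abs(genes$gene_end[g] - tss)
    assert_that(glen > 300, sprintf("gene '%s': body length must be > 0",
                                    genes$gene_id[g]))
    bw <- rel_window(tss, genes$strand[g], 300L, glen)
    tibble(gene_id = genes$gene_id[g],
           expression = track_sum(track, genes$chrom[g], bw[1], bw[2]) / (glen - 300))
  })
  bind_rows(out)
}

#' Identify transcribed enhancers from START-seq signal
#'
#' An eRNA TSS is the position of maximum START-seq signal within 1 kb of an
#' enhancer element. Candidates within 500 bp of any annotated TSS are
#' rejected; among surviving candidates within 500 bp of each other, only
#' the one with the higher maximum START-seq signal is kept.
#'
#' @param enhancers tibble with columns chrom, start, end (element
#'   intervals, 0-based half-open).
#' @param start_track START-seq signal track.
#' @param annotated_tss tibble with columns chrom, tss (all annotated TSSs,
#'   including pseudogenes and noncoding RNAs).
#' @return annotation tibble of accepted eRNA TSSs (gene_class
#'   `"enhancer"`, strand `"+"` by convention since eRNA orientation is not
#'   resolved).
#' @export
identify_transcribed_enhancers <- function(enhancers, start_track, annotated_tss) {
  cands <- map(seq_len(nrow(enhancers)), function(i) {
    lo <- enhancers$start[i] - 1000L
    hi <- enhancers$end[i] + 1000L
    sub <- start_track[start_track$chrom == enhancers$chrom[i] &
                         start_track$pos >= lo & start_track$pos < hi, ]
    if (nrow(sub) == 0) return(NULL)
    best <- sub[which.max(sub$score), ]
    tibble(chrom = best$chrom, pos = best$pos, signal = best$score)
  })
  cands <- bind_rows(cands)
  if (nrow(cands) == 0) {
    return(tibble(gene_id = character(), chrom = character(), tss = integer(),
                  gene_end = integer(), strand = character(),
                  gene_class = character()))
  }
  cands <- distinct(cands)
  near_annot <- vapply(seq_len(nrow(cands)), function(i) {
    same <- annotated_tss[annotated_tss$chrom == cands$chrom[i], ]
    nrow(same) > 0 && any(abs(same$tss - cands$pos[i]) <= 500)
  }, logical(1))
  cands <- cands[!near_annot, ]
  cands <- cands[order(-cands$signal), ]
  kept <- cands[0, ]
  for (i in seq_len(nrow(cands))) {
    clash <- nrow(kept) > 0 &&
      any(kept$chrom == cands$chrom[i] & abs(kept$pos - cands$pos[i]) <= 500)
    if (!clash) kept <- bind_rows(kept, cands[i, ])
  }
  kept <- arrange(kept, .data$chrom, .data$pos)
  tibble(
    gene_id = sprintf("eRNA%03d", seq_len(nrow(kept))),
    chrom = kept$chrom, tss = kept$pos, gene_end = kept$pos + 1L,
    strand = "+", gene_class = "enhancer"
  )
}
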