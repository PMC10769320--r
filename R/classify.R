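#' Footprint classification rules
#'
#' Size, position and peak-overlap thresholds used to assign biological
#' labels to decoded footprints. Size ranges are half-open where the
#' published bounds touch (PPP `[40, 60)`, PIC `[60, 80)`) so the partition
#' is deterministic; `nucleosome` requires size strictly above 90 bp while
#' the single-nucleosome predicate used by positioning analyses spans
#' `[90, 200]` bp.
#'
#' @return a named list of rule constants.
#' @export
classification_rules <- function() {
  list(
    ppp_size = c(40L, 60L),          # [min, max)
    pic_size = c(60L, 80L),          # [min, max)
    nucleosome_min = 90L,            # strictly greater
    single_nucleosome = c(90L, 200L),# [min, max] inclusive
    peak_core_fraction = 0.70,
    peak_core_fraction_strict = 0.50,
    pro_window = c(0L, 100L),        # PRO peak, bp downstream of TSS, inclusive
    cage_window = 50L,               # CAGE peak, +/- bp around TSS
    promoter_access_window = 10L,    # +/- bp around TSS
    elongating_size = c(40L, 60L),   # [min, max)
    tss_exclusion = 300L,            # +/- bp around any TSS
    polIII_size = c(30L, 140L),      # [min, max] inclusive, tRNA
    polIII_5S_max = 160L,
    polIII_upstream = c(45L, 55L),   # footprint start, bp upstream of TSS
    polIII_box_max = 90L             # strictly less
  )
}

# Is `pos` within the central `frac` of [start, end)?
in_core <- function(pos, start, end, frac) {
  size <- end - start
  margin <- (1 - frac) / 2 * size
  pos >= start + margin & pos <= end - margin
}

#' Classify promoter-proximal footprints as PPP or PIC
#'
#' A footprint is a promoter-proximal paused polymerase (PPP) footprint iff
#' its size is in `[40, 60)` bp, the gene's primary PRO-seq peak lies within
#' the central 70% of the footprint interval (50% in strict mode), and that
#' peak sits 0-100 bp downstream of the CAGE-adjusted TSS. It is a
#' preinitiation-complex (PIC) footprint iff its size is in `[60, 80)` bp,
#' the primary CAGE-seq peak lies within the central 70%, and that peak is
#' within 50 bp of the annotated TSS. Footprints larger than 90 bp are
#' labeled `nucleosome`; everything else keeps its current label.
#'
#' @param fp footprint tibble (any number of fibers).
#' @param tss_peaks peak table from [call_tss_peaks()] for both assays
#'   (rows with `assay == "PRO"` and `assay == "CAGE"`); genes lacking a
#'   primary peak for an assay get no label of the corresponding type.
#' @param genes annotation tibble.
#' @param strict use the stricter 50% core-overlap rule for PPP calls
#'   (recommended at genes with very low pause index).
#' @param rules rule constants, see [classification_rules()].
#' @return `fp` with the `label` column updated.
#' @export
classify_promoter_footprints <- function(fp, tss_peaks, genes, strict = FALSE,
                                         rules = classification_rules()) {
  if (nrow(fp) == 0) return(fp)
  frac_ppp <- if (strict) rules$peak_core_fraction_strict else rules$peak_core_fraction
  frac_pic <- rules$peak_core_fraction
  pro <- filter(tss_peaks, .data$assay == "PRO", !is.na(.data$primary_peak),
                !.data$strict_violation)
  cage <- filter(tss_peaks, .data$assay == "CAGE", !is.na(.data$primary_peak),
                 !.data$strict_violation)
  label <- fp$label
  size <- fp$end - fp$start
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    pro_g <- filter(pro, .data$gene_id == gene$gene_id)
    cage_g <- filter(cage, .data$gene_id == gene$gene_id)
    adj_tss <- if (nrow(cage_g) == 1) cage_g$adjusted_tss else gene$tss
    on_chrom <- fp$chrom == gene$chrom & label == "unknown"
    if (nrow(pro_g) == 1) {
      peak <- pro_g$primary_peak
      peak_rel <- tss_relative(peak, adj_tss, gene$strand)
      if (peak_rel >= rules$pro_window[1] && peak_rel <= rules$pro_window[2]) {
        hit <- on_chrom &
          size >= rules$ppp_size[1] & size < rules$ppp_size[2] &
          in_core(peak, fp$start, fp$end, frac_ppp)
        label[hit] <- "PPP"
        on_chrom <- on_chrom & !hit
      }
    }
    if (nrow(cage_g) == 1) {
      peak <- cage_g$primary_peak
      peak_rel <- tss_relative(peak, gene$tss, gene$strand)
      if (abs(peak_rel) <= rules$cage_window) {
        hit <- on_chrom &
          size >= rules$pic_size[1] & size < rules$pic_size[2] &
          in_core(peak, fp$start, fp$end, frac_pic)
        label[hit] <- "PIC"
      }
    }
  }
  nuc <- label == "unknown" & size > rules$nucleosome_min
  label[nuc] <- "nucleosome"
  fp$label <- label
  fp
}

# Single-nucleosome predicate (90-200 bp inclusive), used by +1/-1 analyses.
is_single_nucleosome <- function(size, rules = classification_rules()) {
  size >= rules$single_nucleosome[1] & size <= rules$single_nucleosome[2]
}

#' Per-fiber promoter accessibility
#'
#' A fiber has an accessible promoter at a gene iff it spans the window
#' 10 bp either side of the primary TSS and carries no nucleosome-sized
#' footprint (> 90 bp) overlapping that window. Fibers that do not span the
#' window are not evaluable (distinct from inaccessible).
#'
#' @param fp footprint tibble.
#' @param fb fiber tibble (supplies aligned spans).
#' @param genes annotation tibble.
#' @param rules rule constants.
#' @return tibble: fiber_id, gene_id, evaluable, accessible (`NA` when not
#'   evaluable).
#' @export
promoter_accessibility <- function(fp, fb, genes, rules = classification_rules()) {
  w <- rules$promoter_access_window
  out <- map(seq_len(nrow(genes)), function(g) {
    gene <- genes[g, ]
    lo <- gene$tss - w; hi <- gene$tss + w  # inclusive window
    span_ok <- fb$chrom == gene$chrom & fb$start <= lo & fb$end > hi
    nucs <- fp[fp$chrom == gene$chrom &
                 (fp$end - fp$start) > rules$nucleosome_min &
                 fp$start <= hi & fp$end > lo, ]
    blocked <- fb$fiber_id %in% nucs$fiber_id
    tibble(fiber_id = fb$fiber_id, gene_id = gene$gene_id,
           evaluable = span_ok,
           accessible = ifelse(span_ok, !blocked, NA))
  })
  bind_rows(out)
}

#' Identify elongating Pol II footprints
#'
#' Elongating footprints match the PPP size range (`[40, 60)` bp) but sit in
#' gene bodies more than 300 bp from every annotated TSS (including eRNA
#' TSSs). Density is the count of qualifying footprints per kb of gene body
#' covered by the fiber set; fold enrichment compares that density with the
#' density of identically sized footprints in intergenic space (also
#' excluding TSS +/- 300 bp).
#'
#' @param fp footprint tibble.
#' @param fb fiber tibble (for covered-bp denominators).
#' @param genes annotation tibble (Pol II genes define gene bodies).
#' @param all_tss tibble with columns chrom, tss: every annotated TSS,
#'   including eRNA TSSs.
#' @param rules rule constants.
#' @return list with `footprints` (labels updated) and `stats` (one-row
#'   tibble: counts, covered bp, densities per kb, fold_enrichment — `NA`
#'   and flagged if intergenic coverage is zero).
#' @export
find_elongating <- function(fp, fb, genes, all_tss,
                            rules = classification_rules()) {
  size <- fp$end - fp$start
  mid <- (fp$start + fp$end) / 2
  size_ok <- size >= rules$elongating_size[1] & size < rules$elongating_size[2]
  near_tss <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      t <- all_tss$tss[all_tss$chrom == chrom[i]]
      length(t) > 0 && any(abs(t - pos[i]) <= rules$tss_exclusion)
    }, logical(1))
  }
  in_body <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      gg <- genes[genes$chrom == chrom[i], ]
      if (nrow(gg) == 0) return(FALSE)
      lo <- pmin(gg$tss, gg$gene_end); hi <- pmax(gg$tss, gg$gene_end)
      any(pos[i] >= lo & pos[i] < hi)
    }, logical(1))
  }
  body <- in_body(fp$chrom, mid)
  excl <- near_tss(fp$chrom, mid)
  elong <- size_ok & body & !excl & fp$label %in% c("unknown", "elongating")
  intergenic_fp <- size_ok & !body & !excl

  # covered bp of gene body / intergenic space per fiber (TSS zones excluded)
  body_bp <- 0; inter_bp <- 0
  for (i in seq_len(nrow(fb))) {
    pos <- seq.int(fb$start[i], fb$end[i] - 1L)
    gg <- genes[genes$chrom == fb$chrom[i], ]
    inb <- rep(FALSE, length(pos))
    if (nrow(gg) > 0) {
      for (r in seq_len(nrow(gg))) {
        lo <- min(gg$tss[r], gg$gene_end[r]); hi <- max(gg$tss[r], gg$gene_end[r])
        inb <- inb | (pos >= lo & pos < hi)
      }
    }
    tt <- all_tss$tss[all_tss$chrom == fb$chrom[i]]
    ine <- rep(FALSE, length(pos))
    for (t in tt) ine <- ine | abs(pos - t) <= rules$tss_exclusion
    body_bp <- body_bp + sum(inb & !ine)
    inter_bp <- inter_bp + sum(!inb & !ine)
  }
  dens_body <- if (body_bp > 0) sum(elong) / body_bp * 1000 else NA_real_
  dens_inter <- if (inter_bp > 0) sum(intergenic_fp) / inter_bp * 1000 else NA_real_
  fold <- if (!is.na(dens_inter) && dens_inter > 0) dens_body / dens_inter else NA_real_
  if (is.na(fold)) warn("zero intergenic coverage or density: fold enrichment undefined")
  fp$label[elong] <- "elongating"
  list(
    footprints = fp,
    stats = tibble(n_elongating = sum(elong), n_intergenic = sum(intergenic_fp),
                   gene_body_bp = body_bp, intergenic_bp = inter_bp,
                   density_per_kb = dens_body,
                   intergenic_density_per_kb = dens_inter,
                   fold_enrichment = fold)
  )
}

#' Classify Pol III transcription-associated fibers
#'
#' A fiber carries a Pol III transcription-associated footprint at a tRNA or
#' 5S rRNA gene iff it has (a) a footprint of 30-140 bp (tRNA; the cap rises
#' to 160 bp at 5S genes) whose upstream edge starts 45-55 bp upstream of
#' the TSS, or (b) a footprint under 90 bp overlapping the A-box or B-box
#' alone. Fibers must span from 60 bp upstream of the TSS to the gene end to
#' be evaluable.
#'
#' @param fp footprint tibble.
#' @param fb fiber tibble.
#' @param genes annotation tibble restricted to gene_class `"tRNA"` or
#'   `"rRNA5S"`.
#' @param boxes tibble of internal promoter elements: gene_id, box (`"A"` or
#'   `"B"`), start, end (0-based half-open).
#' @param rules rule constants.
#' @return tibble: fiber_id, gene_id, evaluable, polIII (`NA` when not
#'   evaluable).
#' @export
classify_polIII <- function(fp, fb, genes, boxes = NULL,
                            rules = classification_rules()) {
  assert_that(all(genes$gene_class %in% c("tRNA", "rRNA5S")),
              "classify_polIII expects tRNA or rRNA5S genes")
  out <- map(seq_len(nrow(genes)), function(g) {
    gene <- genes[g, ]
    cap <- if (gene$gene_class == "rRNA5S") rules$polIII_5S_max else rules$polIII_size[2]
    up60 <- tss_absolute(-60L, gene$tss, gene$strand)
    lo <- min(up60, gene$gene_end); hi <- max(up60, gene$gene_end)
    span_ok <- fb$chrom == gene$chrom & fb$start <= lo & fb$end >= hi
    bx <- if (is.null(boxes)) boxes else filter(boxes, .data$gene_id == gene$gene_id)
    fp_g <- fp[fp$chrom == gene$chrom, ]
    size <- fp_g$end - fp_g$start
    up_edge <- if (gene$strand == "+") fp_g$start else fp_g$end - 1L
    up_rel <- -tss_relative(up_edge, gene$tss, gene$strand)  # bp upstream
    clause1 <- size >= rules$polIII_size[1] & size <= cap &
      up_rel >= rules$polIII_upstream[1] & up_rel <= rules$polIII_upstream[2]
    clause2 <- rep(FALSE, nrow(fp_g))
    if (!is.null(bx) && nrow(bx) > 0) {
      for (b in seq_len(nrow(bx))) {
        clause2 <- clause2 | (size < rules$polIII_box_max &
                                fp_g$start < bx$end[b] & fp_g$end > bx$start[b])
      }
    }
    pos_ids <- unique(fp_g$fiber_id[clause1 | clause2])
    tibble(fiber_id = fb$fiber_id, gene_id = gene$gene_id,
           evaluable = span_ok,
           polIII = ifelse(span_ok, fb$fiber_id %in% pos_ids, NA))
  })
  bind_rows(out)
}

#' Pol III transcription frequency per gene
#'
#' Fraction of evaluable fibers at each Pol III gene that carry a
#' transcription-associated footprint.
#'
#' @param calls tibble from [classify_polIII()].
#' @return tibble: gene_id, n_evaluable, n_positive, frequency (`NA` when no
#'   fiber is evaluable).
#' @export
transcription_frequency <- function(calls) {
  calls |>
    filter(.data$evaluable) |>
    group_by(.data$gene_id) |>
    summarise(n_evaluable = n(), n_positive = sum(.data$polIII),
              .groups = "drop") |>
    mutate(frequency = ifelse(.data$n_evaluable > 0,
                              .data$n_positive / .data$n_evaluable, NA_real_))
}

#' Correlate tRNA expression scores with codon frequency
#'
#' Genes are first filtered to those whose coverage lies within the middle
#' 95% of the overall coverage distribution; a tRNA family (genes sharing a
#' codon) is retained only if every member passes. Reports the Pearson
#' correlation of per-family gene-copy counts with codon frequency and of
#' per-family summed expression scores with codon frequency.
#'
#' @param scores tibble: gene_id, family, score, coverage.
#' @param codon_freq tibble: family, frequency.
#' @return one-row tibble: r_counts, r_scores, n_families (`NA` correlations
#'   when fewer than 3 families survive the filter).
#' @export
codon_correlation <- function(scores, codon_freq) {
  q <- quantile(scores$coverage, c(0.025, 0.975), names = FALSE)
  scores <- mutate(scores, pass = .data$coverage >= q[1] & .data$coverage <= q[2])
  fam <- scores |>
    group_by(.data$family) |>
    summarise(all_pass = all(.data$pass), copies = n(),
              score_sum = sum(.data$score), .groups = "drop") |>
    filter(.data$all_pass) |>
    left_join(codon_freq, by = "family") |>
    filter(!is.na(.data$frequency))
  if (nrow(fam) < 3) {
    warn("fewer than 3 retained tRNA families: correlation undefined")
    return(tibble(r_counts = NA_real_, r_scores = NA_real_, n_families = nrow(fam)))
  }
  safe_cor <- function(x, y) {
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)
  }
  tibble(r_counts = safe_cor(fam$copies, fam$frequency),
         r_scores = safe_cor(fam$score_sum, fam$frequency),
         n_families = nrow(fam))
}
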