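#' Construct a fiber table
#'
#' A fiber is one aligned long-read chromatin molecule: its aligned genomic
#' span plus the genomic positions of all adenine sites (A on either strand)
#' and a parallel logical vector saying which sites carry an m6A call. All
#' coordinates are 0-based half-open (BED convention).
#'
#' @param fiber_id character vector of read identifiers.
#' @param chrom,start,end,strand aligned span of each fiber.
#' @param a_sites list of strictly increasing integer vectors of genomic
#'   adenine-site positions, one per fiber.
#' @param methylated list of logical vectors, parallel to `a_sites`.
#' @param dataset optional per-fiber dataset tag (used for stratified
#'   training subsampling); `NA` when there is a single dataset.
#' @return a tibble with one row per fiber and list-columns `a_sites`,
#'   `methylated`.
#' @export
fibers <- function(fiber_id, chrom, start, end, strand = ".",
                   a_sites, methylated, dataset = NA_character_) {
  fb <- tibble(
    fiber_id = as.character(fiber_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    a_sites = as.list(a_sites), methylated = as.list(methylated),
    dataset = as.character(dataset)
  )
  validate_fibers(fb)
  fb
}

#' Validate a fiber table
#'
#' Checks the fiber invariants: valid spans, strictly increasing adenine
#' sites inside the span, and one methylation flag per site.
#'
#' @param fb a fiber tibble as built by [fibers()] or [read_fiber_bed()].
#' @return the input, invisibly; aborts with the offending fiber on failure.
#' @export
validate_fibers <- function(fb) {
  check_interval(fb$chrom, fb$start, fb$end, fb$strand)
  for (i in seq_len(nrow(fb))) {
    s <- fb$a_sites[[i]]
    m <- fb$methylated[[i]]
    if (length(s) != length(m))
      abort(sprintf("fiber '%s': %d a_sites but %d methylation flags",
                    fb$fiber_id[i], length(s), length(m)))
    if (length(s) > 1 && any(diff(s) <= 0))
      abort(sprintf("fiber '%s': a_sites not strictly increasing", fb$fiber_id[i]))
    if (length(s) > 0 && (min(s) < fb$start[i] || max(s) >= fb$end[i]))
      abort(sprintf("fiber '%s': a_site outside aligned span", fb$fiber_id[i]))
  }
  invisible(fb)
}

#' Read fibers from a fiber-BED file
#'
#' The fiber-BED dialect is BED9+2: the nine standard BED columns describe the
#' aligned span (column 4 = fiber id), column 10 holds comma-separated
#' read-relative offsets (aligned orientation, 0 = first base of the span) of
#' all adenine sites, and column 11 the offsets of the methylated subset
#' (`"."` when none).
#'
#' @param path path to a fiber-BED file.
#' @param dataset dataset tag attached to every fiber read from this file.
#' @return a fiber tibble (see [fibers()]).
#' @export
read_fiber_bed <- function(path, dataset = NA_character_) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(fibers(character(), character(), integer(), integer(), character(),
                  list(), list(), character()))
  }
  parse_offsets <- function(x, ln) {
    if (x == "." || x == "") return(integer())
    v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) abort(sprintf("line %d: non-integer offset list", ln))
    v
  }
  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      abort(sprintf("line %d: expected >= 11 tab-separated fields, got %d",
                    ln, length(f)))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (anyNA(c(start, end)) || start < 0 || start >= end)
      abort(sprintf("line %d: invalid span %s-%s", ln, f[2], f[3]))
    offs <- parse_offsets(f[10], ln)
    moffs <- parse_offsets(f[11], ln)
    if (length(offs) > 1 && any(diff(offs) <= 0))
      abort(sprintf("line %d: a_site offsets not strictly increasing", ln))
    if (length(offs) > 0 && (min(offs) < 0 || max(offs) >= end - start))
      abort(sprintf("line %d (fiber '%s'): a_site offset beyond read length", ln, f[4]))
    if (!all(moffs %in% offs))
      abort(sprintf("line %d: methylated offsets not a subset of a_site offsets", ln))
    rows[[ln]] <- tibble(
      fiber_id = f[4], chrom = f[1], start = start, end = end,
      strand = if (f[6] %in% c("+", "-")) f[6] else ".",
      a_sites = list(start + offs),
      methylated = list(offs %in% moffs),
      dataset = dataset
    )
  }
  validate_fibers(bind_rows(rows))
}

#' Write fibers to a fiber-BED file
#'
#' Inverse of [read_fiber_bed()]; the round trip is lossless for all fields
#' except the dataset tag, which is per-file.
#'
#' @param fb fiber tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_bed <- function(fb, path) {
  validate_fibers(fb)
  fmt_offs <- function(x) if (length(x) == 0) "." else paste(x, collapse = ",")
  lines <- vapply(seq_len(nrow(fb)), function(i) {
    offs <- fb$a_sites[[i]] - fb$start[i]
    paste(fb$chrom[i], fb$start[i], fb$end[i], fb$fiber_id[i], 0L,
          fb$strand[i], fb$start[i], fb$end[i], "0,0,0",
          fmt_offs(offs), fmt_offs(offs[fb$methylated[[i]]]),
          sep = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Signed TSS-relative coordinate
#'
#' Converts genomic positions to strand-aware TSS-relative coordinates:
#' negative = upstream, positive = downstream, 0 = the TSS base itself.
#'
#' @param position genomic position(s), 0-based.
#' @param tss TSS position(s), 0-based.
#' @param strand `"+"` or `"-"` (recycled); `"."` is an error because a
#'   strandless gene cannot anchor an upstream/downstream window.
#' @return signed integer distance(s).
#' @export
tss_relative <- function(position, tss, strand) {
  if (any(strand == "."))
    abort("strand '.' cannot anchor a TSS-relative window")
  assert_that(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  n <- max(length(position), length(tss), length(strand))
  position <- rep_len(position, n)
  tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", position - tss, tss - position)
}

# Inverse of tss_relative (used by tests and window construction).
tss_absolute <- function(distance, tss, strand) {
  if (any(strand == ".")) abort("strand '.' cannot anchor a TSS-relative window")
  n <- max(length(distance), length(tss), length(strand))
  distance <- rep_len(distance, n)
  tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", tss + distance, tss - distance)
}

#' Write labeled footprints to BED
#'
#' BED6+1: name = fiber id, score = `round(1000 * mean_posterior)`, final
#' column = class label; records sorted by (chrom, start).
#'
#' @param fp footprint tibble from [decode_footprints()] (optionally labeled).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_footprint_bed <- function(fp, path) {
  req <- c("fiber_id", "chrom", "start", "end", "label")
  assert_that(all(req %in% names(fp)),
              paste("footprint table must have columns:", paste(req, collapse = ", ")))
  fp <- arrange(fp, .data$chrom, .data$start, .data$end)
  score <- if ("mean_posterior" %in% names(fp))
    as.integer(round(1000 * fp$mean_posterior)) else 0L
  strand <- if ("strand" %in% names(fp)) fp$strand else "."
  lines <- paste(fp$chrom, fp$start, fp$end, fp$fiber_id, score, strand,
                 fp$label, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read labeled footprints from BED6+1
#'
#' @param path path written by [write_footprint_bed()].
#' @return footprint tibble with columns fiber_id, chrom, start, end, size,
#'   mean_posterior, label.
#' @export
read_footprint_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(fiber_id = character(), chrom = character(),
                  start = integer(), end = integer(), size = integer(),
                  mean_posterior = double(), label = character()))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tibble(
    fiber_id = f[, 4], chrom = f[, 1],
    start = as.integer(f[, 2]), end = as.integer(f[, 3]),
    size = as.integer(f[, 3]) - as.integer(f[, 2]),
    mean_posterior = as.integer(f[, 5]) / 1000,
    label = f[, 7]
  )
}

#' Read a gene/element annotation BED
#'
#' BED6 with name = gene id; the TSS is the strand-aware 5' end (`start` for
#' `+`, `end - 1` for `-`) and `gene_end` the opposite extreme, so
#' `tss < gene_end` on `+` and `tss > gene_end` on `-`.
#'
#' @param path BED6 file.
#' @param gene_class class assigned to every record (`"polII"`, `"tRNA"`,
#'   `"rRNA5S"` or `"enhancer"`).
#' @return annotation tibble with columns gene_id, chrom, tss, gene_end,
#'   strand, gene_class.
#' @export
read_gene_bed <- function(path, gene_class = "polII") {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L   # to 0-based
  end0 <- GenomicRanges::end(gr)            # half-open
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  tibble(
    gene_id = as.character(gr$name %||% paste0("g", seq_along(gr))),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "-", end0 - 1L, start0),
    gene_end = ifelse(strand == "-", start0, end0),
    strand = strand,
    gene_class = gene_class
  )
}
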