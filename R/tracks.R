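#' Build a per-base signal track
#'
#' Tracks carry per-base read counts for nascent-RNA assays (PRO-seq,
#' CAGE-seq, START-seq) or similar signal. Stored sparsely: one row per base
#' with non-zero signal, 0-based positions; absent bases read as 0.
#'
#' @param chrom,pos,score parallel vectors (pos 0-based).
#' @return a track tibble sorted by (chrom, pos).
#' @export
signal_track <- function(chrom = character(), pos = integer(), score = double()) {
  assert_that(all(score >= 0), "track coverage must be >= 0 everywhere")
  tb <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
               score = as.numeric(score))
  tb <- summarise(group_by(tb, .data$chrom, .data$pos),
                  score = sum(.data$score), .groups = "drop")
  arrange(filter(tb, .data$score != 0), .data$chrom, .data$pos)
}

#' Read a bedGraph file into a signal track
#'
#' @param path bedGraph file.
#' @return a track tibble (see [signal_track()]).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(signal_track())
  w <- GenomicRanges::width(gr)
  signal_track(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = unlist(lapply(seq_along(gr),
                        function(i) seq.int(GenomicRanges::start(gr)[i] - 1L,
                                            length.out = w[i]))),
    score = rep(gr$score, w)
  )
}

#' Write a signal track as bedGraph
#'
#' @param track track tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$pos + 1L, width = 1L),
                               score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Per-base values over [start, end) with zeros filled in.
track_values <- function(track, chrom, start, end) {
  v <- numeric(end - start)
  sub <- track[track$chrom == chrom & track$pos >= start & track$pos < end, ]
  v[sub$pos - start + 1L] <- sub$score
  v
}

# Total coverage over [start, end).
track_sum <- function(track, chrom, start, end) {
  sum(track$score[track$chrom == chrom & track$pos >= start & track$pos < end])
}
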