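#' Sequence context of an adenine site
#'
#' Returns the k-mer (default 7-mer, base +/- 3 nt) around each site on the
#' adenine-bearing strand, so the center character is always A: forward-strand
#' sites are read directly, reverse-strand sites (T on the forward strand) are
#' reverse-complemented. Sites within `(k-1)/2` bp of a contig edge are
#' flagged by returning `NA` and must be excluded from tallies.
#'
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param chrom,pos site coordinates (0-based), vectorized.
#' @param strand `"+"` if the adenine is on the forward strand, `"-"` if on
#'   the reverse (a T on the forward strand).
#' @param width odd context width in nt (default 7).
#' @return character vector of contexts, `NA` at contig edges.
#' @export
context_at <- function(reference, chrom, pos, strand, width = 7L) {
  assert_that(width %% 2 == 1, "context width must be odd")
  ref <- as_reference(reference)
  flank <- (width - 1L) %/% 2L
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    sq <- ref[[ch]]
    if (is.null(sq)) abort(sprintf("contig '%s' missing from reference", ch))
    idx <- which(chrom == ch)
    p <- pos[idx]
    ok <- p - flank >= 0 & p + flank < nchar(sq)
    ctx <- rep(NA_character_, length(idx))
    if (any(ok))
      ctx[ok] <- substring(sq, p[ok] - flank + 1L, p[ok] + flank + 1L)
    out[idx] <- ctx
  }
  rev_i <- which(strand == "-" & !is.na(out))
  if (length(rev_i) > 0)
    out[rev_i] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[rev_i])))
  out[!is.na(out) & grepl("[^ACGT]", out)] <- NA_character_
  out
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    setNames(as.list(toupper(as.character(reference))), names(reference))
  } else if (is.character(reference)) {
    setNames(as.list(toupper(reference)), names(reference))
  } else if (is.list(reference)) {
    lapply(reference, toupper)
  } else abort("reference must be a DNAStringSet or named character vector")
}

# Strand of the adenine at each position: "+" if the reference base is A,
# "-" if T, NA otherwise.
site_strand <- function(reference, chrom, pos) {
  ref <- as_reference(reference)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    base <- substring(ref[[ch]], pos[idx] + 1L, pos[idx] + 1L)
    out[idx] <- ifelse(base == "A", "+", ifelse(base == "T", "-", NA))
  }
  out
}

#' Calibrate emission probabilities from control fiber sets
#'
#' Estimates, for every observed sequence context, the probability that an
#' adenine is called methylated in the accessible state (from the positive
#' control: methyltransferase-treated dechromatinized genomic DNA, where all
#' DNA is accessible) and in the inaccessible state (from the negative
#' control: untreated DNA, where every call is a false positive). Rates are
#' Laplace-smoothed: `(meth + pc) / (total + 2 pc)`. Contexts never observed
#' in a control set fall back to that set's global rate, as do contexts
#' containing non-ACGT bases and sites at contig edges.
#'
#' @param positive,negative fiber tibbles for the two control sets.
#' @param reference optional reference sequences; when `NULL` the table is
#'   global-only (one accessible/inaccessible rate pair, no context
#'   stratification — the sequence-free mode used with simulated fibers).
#' @param pseudocount Laplace pseudocount (default 1).
#' @param context_width odd context width (default 7 = base +/- 3 nt).
#' @return an `emission_table` object.
#' @export
build_emission_table <- function(positive, negative, reference = NULL,
                                 pseudocount = 1, context_width = 7L) {
  assert_that(nrow(positive) > 0 && nrow(negative) > 0,
              "both control sets must be non-empty")
  assert_that(pseudocount > 0, "pseudocount must be positive")
  tally <- function(fb) {
    pos <- unlist(fb$a_sites)
    meth <- unlist(fb$methylated)
    chrom <- rep(fb$chrom, lengths(fb$a_sites))
    if (is.null(reference)) {
      return(list(ctx = NULL, meth = meth))
    }
    strand <- site_strand(reference, chrom, pos)
    keep <- !is.na(strand)
    ctx <- context_at(reference, chrom[keep], pos[keep], strand[keep],
                      width = context_width)
    list(ctx = ctx, meth = meth[keep])
  }
  tp <- tally(positive); tn <- tally(negative)
  sm <- function(k, n) (k + pseudocount) / (n + 2 * pseudocount)
  g_acc <- sm(sum(tp$meth), length(tp$meth))
  g_inacc <- sm(sum(tn$meth), length(tn$meth))
  if (g_acc <= g_inacc)
    abort(paste0("calibration failure: global accessible rate (", signif(g_acc, 4),
                 ") <= inaccessible rate (", signif(g_inacc, 4),
                 ") - controls swapped or degenerate"))
  probs <- NULL
  if (!is.null(reference)) {
    per_ctx <- function(t) {
      ok <- !is.na(t$ctx)
      df <- tibble(context = t$ctx[ok], meth = t$meth[ok])
      summarise(group_by(df, .data$context),
                k = sum(.data$meth), n = n(), .groups = "drop")
    }
    cp <- per_ctx(tp); cn <- per_ctx(tn)
    all_ctx <- union(cp$context, cn$context)
    probs <- tibble(context = sort(all_ctx)) |>
      left_join(cp, by = "context") |>
      rename(k_pos = "k", n_pos = "n") |>
      left_join(cn, by = "context") |>
      rename(k_neg = "k", n_neg = "n") |>
      mutate(
        p_acc = ifelse(is.na(.data$n_pos), g_acc, sm(.data$k_pos, .data$n_pos)),
        p_inacc = ifelse(is.na(.data$n_neg), g_inacc, sm(.data$k_neg, .data$n_neg))
      ) |>
      select("context", "p_acc", "p_inacc")
  }
  new_emission_table(context_width, probs, g_acc, g_inacc, pseudocount)
}

#' Build an emission table directly from known rates
#'
#' Used with simulated data (sequence-free mode) or externally calibrated
#' rates.
#'
#' @param p_acc,p_inacc global methylation probabilities in the accessible and
#'   inaccessible state; must satisfy `0 < p_inacc < p_acc < 1`.
#' @param probs optional per-context tibble (context, p_acc, p_inacc).
#' @param context_width odd context width.
#' @return an `emission_table` object.
#' @export
emission_table <- function(p_acc, p_inacc, probs = NULL, context_width = 7L) {
  new_emission_table(context_width, probs, p_acc, p_inacc, NA_real_)
}

new_emission_table <- function(context_width, probs, p_acc_global,
                               p_inacc_global, pseudocount) {
  assert_that(p_acc_global > 0 && p_acc_global < 1 &&
                p_inacc_global > 0 && p_inacc_global < 1,
              "global rates must be strictly inside (0, 1)")
  assert_that(p_acc_global > p_inacc_global,
              "accessible rate must exceed inaccessible rate")
  if (!is.null(probs)) {
    assert_that(all(probs$p_acc > 0 & probs$p_acc < 1 &
                      probs$p_inacc > 0 & probs$p_inacc < 1),
                "per-context rates must be strictly inside (0, 1)")
    assert_that(all(nchar(probs$context) == context_width),
                "context keys must match context_width")
  }
  structure(
    list(context_width = as.integer(context_width), probs = probs,
         p_acc_global = p_acc_global, p_inacc_global = p_inacc_global,
         pseudocount = pseudocount),
    class = "emission_table"
  )
}

#' @export
print.emission_table <- function(x, ...) {
  cat("<emission_table> context width", x$context_width, "\n")
  cat("  global: p(meth|accessible) =", signif(x$p_acc_global, 4),
      " p(meth|inaccessible) =", signif(x$p_inacc_global, 4), "\n")
  cat("  contexts:", if (is.null(x$probs)) 0 else nrow(x$probs), "\n")
  invisible(x)
}

# L x 2 matrix of P(methylated | state) for one fiber's a_sites.
# Column 1 = accessible, column 2 = inaccessible.
emission_probs_for_sites <- function(table, chrom, sites, reference = NULL) {
  L <- length(sites)
  if (is.null(table$probs) || is.null(reference) || L == 0) {
    return(matrix(c(rep(table$p_acc_global, L), rep(table$p_inacc_global, L)),
                  ncol = 2))
  }
  strand <- site_strand(reference, chrom, sites)
  ctx <- rep(NA_character_, L)
  ok <- !is.na(strand)
  ctx[ok] <- context_at(reference, chrom, sites[ok], strand[ok],
                        width = table$context_width)
  i <- match(ctx, table$probs$context)
  pa <- table$probs$p_acc[i]; pi_ <- table$probs$p_inacc[i]
  pa[is.na(pa)] <- table$p_acc_global
  pi_[is.na(pi_)] <- table$p_inacc_global
  cbind(pa, pi_, deparse.level = 0)
}

#' Write an emission table to TSV
#'
#' Header comment lines store the context width, pseudocount and global
#' rates; the body is one row per context (context, p_acc, p_inacc).
#'
#' @param table an `emission_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emission_tsv <- function(table, path) {
  hdr <- c(
    sprintf("#context_width=%d", table$context_width),
    sprintf("#pseudocount=%s", format(table$pseudocount, digits = 17)),
    sprintf("#p_acc_global=%s", format(table$p_acc_global, digits = 17)),
    sprintf("#p_inacc_global=%s", format(table$p_inacc_global, digits = 17)),
    "context\tp_acc\tp_inacc"
  )
  body <- if (is.null(table$probs)) character() else
    sprintf("%s\t%s\t%s", table$probs$context,
            format(table$probs$p_acc, digits = 17),
            format(table$probs$p_inacc, digits = 17))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read an emission table from TSV
#'
#' @param path path written by [write_emission_tsv()].
#' @return an `emission_table`.
#' @export
read_emission_tsv <- function(path) {
  lines <- readr::read_lines(path)
  meta <- lines[startsWith(lines, "#")]
  get <- function(key) {
    v <- sub(paste0("#", key, "="), "", meta[startsWith(meta, paste0("#", key, "="))])
    suppressWarnings(as.numeric(v))
  }
  body <- lines[!startsWith(lines, "#")][-1]  # drop column header
  probs <- NULL
  if (length(body) > 0) {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    probs <- tibble(context = f[, 1], p_acc = as.numeric(f[, 2]),
                    p_inacc = as.numeric(f[, 3]))
  }
  new_emission_table(as.integer(get("context_width")), probs,
                     get("p_acc_global"), get("p_inacc_global"),
                     get("pseudocount"))
}
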