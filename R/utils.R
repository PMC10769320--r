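# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# Validate a genomic interval triple; 0-based half-open throughout.
check_interval <- function(chrom, start, end, strand = ".") {
  assert_that(all(start >= 0) && all(start < end),
              "invalid interval: need 0 <= start < end")
  assert_that(all(strand %in% c("+", "-", ".")),
              "strand must be one of '+', '-', '.'")
  invisible(TRUE)
}

is_probability <- function(p) is.numeric(p) && all(p >= 0 & p <= 1)

# Draw from Dirichlet(1, ..., 1) via normalized exponentials.
rdirichlet1 <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

# Local RNG scope: run code under a seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
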