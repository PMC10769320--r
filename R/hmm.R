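#' Construct two-state HMM parameters
#'
#' The model has two hidden states, accessible and inaccessible, over the
#' chain of adenine sites of a fiber (chain steps are consecutive a-sites,
#' not consecutive bp; inter-site distance is not modeled). Emission
#' probabilities are fixed by the [emission_table()]; only the start vector
#' and the 2x2 transition matrix are free parameters.
#'
#' @param start length-2 probability vector (accessible, inaccessible).
#' @param trans 2x2 row-stochastic transition matrix, rows/cols ordered
#'   (accessible, inaccessible).
#' @param train_loglik log-likelihood of the winning training run (optional).
#' @param loglik_trace per-iteration log-likelihood trace of the winning
#'   restart (optional).
#' @param training_ids fiber ids used for training, recorded so callers can
#'   exclude them from downstream analyses (optional).
#' @param converged,n_restarts training metadata (optional).
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(start, trans, train_loglik = NA_real_,
                       loglik_trace = numeric(), training_ids = character(),
                       converged = NA, n_restarts = NA_integer_) {
  start <- as.numeric(start)
  trans <- matrix(as.numeric(trans), 2, 2)
  assert_that(abs(sum(start) - 1) < 1e-12, "start probabilities must sum to 1")
  assert_that(all(abs(rowSums(trans) - 1) < 1e-12),
              "transition rows must sum to 1")
  assert_that(all(start > 0 & start < 1) && all(trans > 0 & trans < 1),
              "all HMM probabilities must be strictly inside (0, 1)")
  states <- c("accessible", "inaccessible")
  names(start) <- states
  dimnames(trans) <- list(from = states, to = states)
  structure(
    list(start = start, trans = trans, train_loglik = train_loglik,
         loglik_trace = loglik_trace, training_ids = training_ids,
         converged = converged, n_restarts = n_restarts),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> two-state accessibility HMM\n")
  cat("  start:", paste(sprintf("%s=%.4f", names(x$start), x$start),
                        collapse = "  "), "\n")
  cat("  transitions:\n")
  print(round(x$trans, 4))
  if (is.finite(x$train_loglik))
    cat("  training log-likelihood:", format(x$train_loglik), "\n")
  invisible(x)
}

#' @rdname hmm_params
#' @param x an `hmm_params` object.
#' @param ... unused.
#' @export
tidy.hmm_params <- function(x, ...) {
  tibble(
    term = c("start_accessible", "start_inaccessible",
             "accessible_to_accessible", "accessible_to_inaccessible",
             "inaccessible_to_accessible", "inaccessible_to_inaccessible"),
    estimate = c(unname(x$start), c(t(x$trans)))
  )
}

#' @rdname hmm_params
#' @export
glance.hmm_params <- function(x, ...) {
  tibble(train_loglik = x$train_loglik,
         n_iter = length(x$loglik_trace),
         n_restarts = x$n_restarts,
         converged = isTRUE(x$converged),
         n_training_fibers = length(x$training_ids))
}

# Observation vector and per-site emission matrix for one fiber row.
fiber_obs <- function(fb, i, table, reference = NULL) {
  sites <- fb$a_sites[[i]]
  list(obs = as.integer(fb$methylated[[i]]),
       pm = emission_probs_for_sites(table, fb$chrom[i], sites, reference))
}

#' Forward log-likelihood of fibers under the HMM
#'
#' Scaled forward algorithm over each fiber's chain of adenine sites. A fiber
#' with zero sites has log-likelihood 0 (empty product) by convention.
#'
#' @param fb fiber tibble.
#' @param table emission table.
#' @param params `hmm_params`.
#' @param reference optional reference (required for per-context emissions).
#' @return numeric vector, one log-likelihood per fiber.
#' @export
forward_loglik <- function(fb, table, params, reference = NULL) {
  vapply(seq_len(nrow(fb)), function(i) {
    o <- fiber_obs(fb, i, table, reference)
    fhmm_forward_cpp(o$obs, o$pm, params$start, params$trans)
  }, numeric(1))
}

#' Per-site posterior state probabilities
#'
#' Forward-backward posteriors for every adenine site of every fiber.
#'
#' @inheritParams forward_loglik
#' @return tibble with columns fiber_id, pos, p_accessible, p_inaccessible.
#' @export
site_posteriors <- function(fb, table, params, reference = NULL) {
  out <- map(seq_len(nrow(fb)), function(i) {
    o <- fiber_obs(fb, i, table, reference)
    r <- fhmm_fwdbwd_cpp(o$obs, o$pm, params$start, params$trans)
    tibble(fiber_id = fb$fiber_id[i], pos = fb$a_sites[[i]],
           p_accessible = r$gamma[, 1], p_inaccessible = r$gamma[, 2])
  })
  bind_rows(out)
}

#' Train the HMM start and transition probabilities
#'
#' Baum-Welch expectation-maximization with emissions frozen at the
#' calibrated table. Training is repeated `n_restarts` times on a subsample
#' of `n_reads` fibers, each restart initialized from Dirichlet(1, 1) draws
#' (start vector and each transition row); the restart with the highest
#' final log-likelihood wins. When a `dataset` tag is present, the subsample
#' is drawn in equal proportions from each dataset; otherwise uniformly.
#' Training fiber ids are recorded in the result so callers can exclude them
#' from downstream analyses.
#'
#' @param fb fiber tibble.
#' @param table emission table.
#' @param n_restarts number of EM restarts (default 20).
#' @param n_reads training subsample size (default 1000); if fewer fibers are
#'   available all are used, with a warning.
#' @param seed integer RNG seed (mandatory: training is stochastic).
#' @param reference optional reference for per-context emissions.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` (default 1e-6) or after `max_iter` (default 500)
#'   iterations.
#' @return an [hmm_params()] object carrying the winning parameters, its
#'   log-likelihood trace, and the training fiber ids.
#' @export
train_hmm <- function(fb, table, n_restarts = 20, n_reads = 1000, seed,
                      reference = NULL, max_iter = 500, tol = 1e-6) {
  assert_that(nrow(fb) > 0, "no fibers to train on")
  assert_that(!missing(seed), "a seed is required for training")
  with_seed(seed, {
    idx <- seq_len(nrow(fb))
    if (nrow(fb) > n_reads) {
      if (!all(is.na(fb$dataset)) && length(unique(fb$dataset)) > 1) {
        # proportional stratified sampling by dataset tag
        per <- split(idx, fb$dataset)
        take <- vapply(per, function(g)
          max(1L, round(n_reads * length(g) / nrow(fb))), integer(1))
        idx <- unlist(map2(per, take, function(g, k) sample(g, min(k, length(g)))))
      } else {
        idx <- sample(idx, n_reads)
      }
    } else if (nrow(fb) < n_reads) {
      warn(sprintf("only %d fibers available (< n_reads = %d); using all",
                   nrow(fb), n_reads))
    }
    idx <- sort(idx)
    obs_list <- vector("list", length(idx))
    pm_list <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      o <- fiber_obs(fb, idx[j], table, reference)
      obs_list[[j]] <- o$obs
      pm_list[[j]] <- o$pm
    }
    best <- NULL
    restart_traces <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      start0 <- rdirichlet1(2)
      trans0 <- rbind(rdirichlet1(2), rdirichlet1(2))
      fit <- fhmm_bw_em_cpp(obs_list, pm_list, start0, trans0, max_iter, tol)
      ll <- fit$loglik_trace[length(fit$loglik_trace)]
      restart_traces[[r]] <- fit$loglik_trace
      if (!is.finite(ll)) {
        warn(sprintf("restart %d: non-finite likelihood, discarded", r))
        next
      }
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, fit = fit)
    }
    assert_that(!is.null(best), "all restarts produced non-finite likelihoods")
    out <- hmm_params(
      start = best$fit$start, trans = best$fit$trans,
      train_loglik = best$ll, loglik_trace = best$fit$loglik_trace,
      training_ids = fb$fiber_id[idx], converged = best$fit$converged,
      n_restarts = n_restarts
    )
    out$restart_traces <- restart_traces
    out
  })
}

#' Decode footprints on each fiber
#'
#' Viterbi-decodes the accessible/inaccessible path over each fiber's adenine
#' sites; maximal runs of the inaccessible state become footprints. A
#' footprint spans `[first a-site of the run, last a-site of the run + 1)`
#' (boundaries anchored to observed sites), its `mean_posterior` is the mean
#' forward-backward posterior of the inaccessible state over the run's sites,
#' and ties in the Viterbi recursion break toward the accessible state
#' (conservative footprinting).
#'
#' @inheritParams forward_loglik
#' @param min_size drop footprints narrower than this many bp (default 1).
#' @return footprint tibble: fiber_id, chrom, strand, start, end, size,
#'   n_sites, mean_posterior, label (initially `"unknown"`).
#' @export
decode_footprints <- function(fb, table, params, reference = NULL, min_size = 1) {
  out <- map(seq_len(nrow(fb)), function(i) {
    sites <- fb$a_sites[[i]]
    if (length(sites) == 0) return(NULL)
    o <- fiber_obs(fb, i, table, reference)
    path <- fhmm_viterbi_cpp(o$obs, o$pm, params$start, params$trans)
    if (!any(path == 1L)) return(NULL)
    gamma <- fhmm_fwdbwd_cpp(o$obs, o$pm, params$start, params$trans)$gamma
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values == 1L)
    tibble(
      fiber_id = fb$fiber_id[i], chrom = fb$chrom[i], strand = fb$strand[i],
      start = sites[starts[runs]],
      end = sites[ends[runs]] + 1L,
      n_sites = r$lengths[runs],
      mean_posterior = vapply(runs, function(k)
        mean(gamma[starts[k]:ends[k], 2]), numeric(1))
    )
  })
  fp <- bind_rows(out)
  if (nrow(fp) == 0) {
    return(tibble(fiber_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  size = integer(), n_sites = integer(),
                  mean_posterior = double(), label = character()))
  }
  fp |>
    mutate(size = .data$end - .data$start, label = "unknown") |>
    filter(.data$size >= min_size) |>
    select("fiber_id", "chrom", "strand", "start", "end", "size",
           "n_sites", "mean_posterior", "label")
}

#' Serialize HMM parameters to JSON
#'
#' @param params `hmm_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm_params <- function(params, path) {
  jsonlite::write_json(
    list(start = unname(params$start), trans = unname(params$trans),
         train_loglik = params$train_loglik,
         training_ids = params$training_ids),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read HMM parameters from JSON
#'
#' @param path path written by [write_hmm_params()].
#' @return an `hmm_params` object.
#' @export
read_hmm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(x$start, x$trans,
             train_loglik = x$train_loglik %||% NA_real_,
             training_ids = x$training_ids %||% character())
}
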