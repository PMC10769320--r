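# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive implementations (enumeration, closed forms) kept
# separate from the package code paths they check.

# Per-path log-probabilities of all 2^L state paths (columns vectorized over
# paths). States: 1 = accessible, 2 = inaccessible.
enum_path_logprobs <- function(obs, pm, start, trans) {
  L <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  lp <- log(start[paths[, 1]])
  if (L > 1) {
    for (t in 2:L) lp <- lp + log(trans[cbind(paths[, t - 1], paths[, t])])
  }
  for (t in 1:L) {
    pe <- pm[t, ][paths[, t]]
    lp <- lp + log(if (obs[t] == 1) pe else 1 - pe)
  }
  list(paths = paths, lp = lp)
}

# Log-likelihood by brute-force enumeration of all 2^L state paths.
enum_forward <- function(obs, pm, start, trans) {
  if (length(obs) == 0) return(0)
  e <- enum_path_logprobs(obs, pm, start, trans)
  m <- max(e$lp)
  m + log(sum(exp(e$lp - m)))
}

# Maximum-probability state path by enumeration; returns 0/1 coding
# (0 = accessible) and the maximum log-probability.
enum_viterbi <- function(obs, pm, start, trans) {
  e <- enum_path_logprobs(obs, pm, start, trans)
  best <- which.max(e$lp)
  list(path = e$paths[best, ] - 1L, logp = e$lp[best],
       unique = sum(abs(e$lp - e$lp[best]) < 1e-12) == 1)
}

# Two-sided Fisher p by explicit hypergeometric enumeration from log
# factorials (independent of stats::dhyper).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lp <- function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(ks, lp, numeric(1)))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson correlation straight from the covariance formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Fine grid search for the both-positive cell with a target odds ratio.
grid_joint_from_or <- function(p_a, p_b, or, n_grid = 2e6) {
  lo <- max(0, p_a + p_b - 1); hi <- min(p_a, p_b)
  p11 <- seq(lo + 1e-9, hi - 1e-9, length.out = n_grid)
  ors <- p11 * (1 - p_a - p_b + p11) / ((p_a - p11) * (p_b - p11))
  p11[which.min(abs(ors - or))]
}

# Random small fiber for HMM oracle checks.
random_small_fiber <- function(L, id = "f1") {
  sites <- sort(sample.int(10 * L, L)) - 1L
  fibers(id, "chrT", 0L, as.integer(10 * L + 1), "+",
         list(sites), list(stats::runif(L) < 0.5))
}

random_hmm_params <- function() {
  s <- stats::runif(1, 0.1, 0.9)
  t1 <- stats::runif(1, 0.05, 0.95)
  t2 <- stats::runif(1, 0.05, 0.95)
  hmm_params(c(s, 1 - s), rbind(c(t1, 1 - t1), c(t2, 1 - t2)))
}
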