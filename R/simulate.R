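#' Simulation configuration
#'
#' Describes the generative model for synthetic chromatin fibers: a single
#' synthetic contig, fibers with Gaussian length variation, uniform
#' adenine-site density, a global emission pair (sequence-free mode),
#' promoters with configurable PIC/PPP marginal frequencies and pairwise
#' co-occupancy odds ratios, phased nucleosome arrays, and optional Pol III
#' genes and transcribed enhancers.
#'
#' Defaults emulate a fly-like genome read at long-read scale: 15 kb mean
#' reads, adenine-site density 0.55/bp (AT-rich genome, adenines counted on
#' both strands), methylation probability 0.9 for accessible and 0.04 for
#' inaccessible adenines, 147 bp nucleosome cores on a 185 bp repeat.
#'
#' @param genome_length synthetic contig length in bp.
#' @param n_fibers number of fibers to simulate.
#' @param read_mean,read_sd fiber length distribution (bp).
#' @param a_density adenine-site density per bp.
#' @param p_acc,p_inacc methylation probability per adenine in the
#'   accessible / inaccessible state.
#' @param promoters tibble with columns `position` (TSS, 0-based), `strand`,
#'   `p_ppp`, `p_pic`, and optionally `ppp_size` (default 50), `pic_size`
#'   (70), `pause_offset` (PRO peak position downstream of TSS, default 40),
#'   `plus1_mean`, `plus1_sd` (+1 nucleosome start, TSS-relative; defaults
#'   40 and 10) and `plus1_shift_ppp` (added to `plus1_mean` on fibers
#'   carrying a PPP footprint; default 0).
#' @param pair_structure tibble with columns `i`, `j` (promoter row indices)
#'   and `or`: the PPP-occupancy indicators of the two promoters are drawn
#'   jointly with this odds ratio (see [joint_from_or()]); unpaired
#'   promoters are independent.
#' @param steric_exclusion when `TRUE`, a promoter whose PRO/CAGE peak
#'   distance (`pause_offset`) is below `steric_max_dist` can never carry
#'   PPP and PIC simultaneously (the PIC draw is suppressed on PPP fibers).
#' @param steric_max_dist peak-distance threshold in bp for steric exclusion.
#' @param nucleosome_repeat,nucleosome_size,nucleosome_occupancy array
#'   geometry: repeat length, core footprint size, per-slot occupancy
#'   probability.
#' @param polIII optional tibble of Pol III genes: `position` (TSS),
#'   `strand`, `p_footprint`, and optionally `footprint_size` (default 100)
#'   and `upstream_offset` (footprint start upstream of the TSS, default 50).
#' @param enhancers optional tibble of transcribed enhancers: `position`
#'   (element center), `erna_offset` (eRNA TSS offset from center), `height`
#'   (START-seq peak reads).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L, n_fibers = 200L,
                       read_mean = 15000, read_sd = 2000, a_density = 0.55,
                       p_acc = 0.9, p_inacc = 0.04,
                       promoters = NULL, pair_structure = NULL,
                       steric_exclusion = FALSE, steric_max_dist = 60,
                       nucleosome_repeat = 185L, nucleosome_size = 147L,
                       nucleosome_occupancy = 0.8,
                       polIII = NULL, enhancers = NULL, seed) {
  assert_that(!missing(seed), "sim_config requires a seed")
  assert_that(is_probability(c(p_acc, p_inacc, a_density, nucleosome_occupancy)),
              "probabilities must lie in [0, 1]")
  if (is.null(promoters)) {
    promoters <- tibble(position = round(genome_length / 2), strand = "+",
                        p_ppp = 0.3, p_pic = 0.2)
  }
  promoters <- as_tibble(promoters)
  defaults <- list(ppp_size = 50L, pic_size = 70L, pause_offset = 40L,
                   plus1_mean = 60, plus1_sd = 10, plus1_shift_ppp = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(promoters)) promoters[[nm]] <- defaults[[nm]]
  }
  assert_that(is_probability(promoters$p_ppp) && is_probability(promoters$p_pic),
              "promoter occupancy probabilities must lie in [0, 1]")
  if (!is.null(pair_structure)) {
    pair_structure <- as_tibble(pair_structure)
    assert_that(all(pair_structure$or > 0), "target odds ratios must be > 0")
  }
  if (!is.null(polIII)) {
    polIII <- as_tibble(polIII)
    if (!"footprint_size" %in% names(polIII)) polIII$footprint_size <- 100L
    if (!"upstream_offset" %in% names(polIII)) polIII$upstream_offset <- 50L
  }
  if (!is.null(enhancers)) enhancers <- as_tibble(enhancers)
  structure(
    list(genome_length = as.integer(genome_length), n_fibers = as.integer(n_fibers),
         read_mean = read_mean, read_sd = read_sd, a_density = a_density,
         p_acc = p_acc, p_inacc = p_inacc, promoters = promoters,
         pair_structure = pair_structure, steric_exclusion = steric_exclusion,
         steric_max_dist = steric_max_dist,
         nucleosome_repeat = as.integer(nucleosome_repeat),
         nucleosome_size = as.integer(nucleosome_size),
         nucleosome_occupancy = nucleosome_occupancy,
         polIII = polIII, enhancers = enhancers, seed = as.integer(seed),
         chrom = "chrS"),
    class = "sim_config"
  )
}

#' Joint 2x2 distribution with given marginals and odds ratio
#'
#' Solves for the unique both-positive cell probability `p11` such that the
#' joint of two Bernoulli indicators has marginals `p_a`, `p_b` and odds
#' ratio `or` (the feasible root of the standard quadratic in `p11`).
#'
#' @param p_a,p_b marginal probabilities, strictly inside (0, 1).
#' @param or target odds ratio, > 0.
#' @return named numeric vector `c(p11, p10, p01, p00)`.
#' @export
joint_from_or <- function(p_a, p_b, or) {
  assert_that(p_a > 0 && p_a < 1 && p_b > 0 && p_b < 1,
              "marginals must be strictly inside (0, 1)")
  assert_that(or > 0, "odds ratio must be > 0")
  if (abs(or - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    a <- or - 1
    b <- -(1 + (p_a + p_b) * (or - 1))
    cc <- or * p_a * p_b
    disc <- b^2 - 4 * a * cc
    assert_that(disc >= 0, "infeasible marginal/odds-ratio combination")
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    lo <- max(0, p_a + p_b - 1)
    hi <- min(p_a, p_b)
    feas <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    assert_that(length(feas) >= 1, "no feasible root for the requested odds ratio")
    p11 <- min(max(feas[1], lo), hi)
  }
  j <- c(p11 = p11, p10 = p_a - p11, p01 = p_b - p11, p00 = 1 - p_a - p_b + p11)
  assert_that(all(j >= -1e-12), "infeasible joint distribution")
  pmax(j, 0)
}

#' Draw paired Bernoulli features with a planted odds ratio
#'
#' @param n number of draws (fibers).
#' @param p_a,p_b marginals.
#' @param or planted odds ratio.
#' @param seed optional seed.
#' @return tibble with logical columns `a`, `b`.
#' @export
simulate_pair_features <- function(n, p_a, p_b, or, seed = NULL) {
  j <- joint_from_or(p_a, p_b, or)
  with_seed(seed, {
    cell <- sample(4L, n, replace = TRUE, prob = j)
    tibble(a = cell %in% c(1L, 2L), b = cell %in% c(1L, 3L))
  })
}

#' Simulate fibers directly from the two-state HMM
#'
#' Generates observation chains from known start/transition probabilities
#' with a global emission pair; the generate-and-refit route for checking
#' parameter recovery.
#'
#' @param n number of fibers.
#' @param length_bp fiber length (bp).
#' @param a_density adenine-site density per bp.
#' @param start,trans generative HMM parameters.
#' @param p_acc,p_inacc emission probabilities.
#' @param seed integer seed.
#' @return list with `fibers` (fiber tibble) and `states` (list of true
#'   state vectors, 1 = accessible, 2 = inaccessible).
#' @export
simulate_hmm_fibers <- function(n, length_bp = 10000, a_density = 0.55,
                                start = c(0.7, 0.3),
                                trans = rbind(c(0.99, 0.01), c(0.02, 0.98)),
                                p_acc = 0.9, p_inacc = 0.04, seed) {
  with_seed(seed, {
    rows <- vector("list", n)
    states <- vector("list", n)
    for (i in seq_len(n)) {
      sites <- which(runif(length_bp) < a_density) - 1L
      L <- length(sites)
      st <- integer(L)
      if (L > 0) {
        st[1] <- sample(2L, 1, prob = start)
        if (L > 1) for (t in 2:L) st[t] <- sample(2L, 1, prob = trans[st[t - 1], ])
      }
      p <- ifelse(st == 1L, p_acc, p_inacc)
      rows[[i]] <- tibble(
        fiber_id = sprintf("sim%05d", i), chrom = "chrS",
        start = 0L, end = as.integer(length_bp), strand = "+",
        a_sites = list(sites), methylated = list(runif(L) < p),
        dataset = NA_character_
      )
      states[[i]] <- st
    }
    list(fibers = validate_fibers(bind_rows(rows)), states = states)
  })
}

# Draw PPP indicators for all promoters of one fiber honoring pair_structure.
draw_ppp <- function(config) {
  np <- nrow(config$promoters)
  ppp <- logical(np)
  paired <- integer(0)
  if (!is.null(config$pair_structure)) {
    for (r in seq_len(nrow(config$pair_structure))) {
      i <- config$pair_structure$i[r]; j <- config$pair_structure$j[r]
      d <- simulate_pair_features(1, config$promoters$p_ppp[i],
                                  config$promoters$p_ppp[j],
                                  config$pair_structure$or[r])
      ppp[i] <- d$a; ppp[j] <- d$b
      paired <- c(paired, i, j)
    }
  }
  rest <- setdiff(seq_len(np), paired)
  ppp[rest] <- runif(length(rest)) < config$promoters$p_ppp[rest]
  ppp
}

#' Simulate chromatin fibers with planted ground truth
#'
#' For each fiber: draws an aligned span, plants PPP/PIC footprints at
#' covered promoters (jointly across promoter pairs per the configured odds
#' ratios, with optional steric exclusion of simultaneous PPP+PIC at
#' close-peaked promoters), plants Pol III footprints, phases a nucleosome
#' array off the nearest covered promoter's +1 position (or a random phase
#' when no promoter is covered), then places adenine sites at uniform
#' density and methylates each with `p_acc` outside planted footprints and
#' `p_inacc` inside. Nucleosome slots colliding with planted PPP/PIC/Pol III
#' footprints are displaced (dropped and counted in the truth record).
#'
#' @param config a [sim_config()].
#' @return list with `fibers` (fiber tibble), `truth` (list: `footprints`
#'   planted-footprint tibble with class labels, `occupancy` per
#'   fiber-x-promoter indicator tibble, `n_displaced`, `config`).
#' @export
simulate_fibers <- function(config) {
  with_seed(config$seed, {
    pr <- config$promoters
    rows <- vector("list", config$n_fibers)
    fp_truth <- vector("list", config$n_fibers)
    occ_truth <- vector("list", config$n_fibers)
    n_displaced <- 0L
    G <- config$genome_length
    for (i in seq_len(config$n_fibers)) {
      len <- max(2000, round(rnorm(1, config$read_mean, config$read_sd)))
      fstart <- sample.int(max(1L, G - len + 1L), 1) - 1L
      fend <- min(G, fstart + len)
      fid <- sprintf("fib%05d", i)

      ppp <- draw_ppp(config)
      pic <- runif(nrow(pr)) < pr$p_pic
      if (config$steric_exclusion) {
        blocked <- ppp & pr$pause_offset < config$steric_max_dist
        pic[blocked] <- FALSE
      }

      planted <- list()
      covered <- which(pr$position - 400 >= fstart & pr$position + 400 < fend)
      for (k in covered) {
        tssk <- pr$position[k]; stk <- pr$strand[k]
        if (ppp[k]) {
          peak <- tss_absolute(pr$pause_offset[k], tssk, stk)
          s <- peak - pr$ppp_size[k] %/% 2L
          planted <- c(planted, list(tibble(
            fiber_id = fid, class = "PPP", start = as.integer(s),
            end = as.integer(s + pr$ppp_size[k]), element = paste0("prom", k))))
        }
        if (pic[k]) {
          s <- tssk - pr$pic_size[k] %/% 2L
          planted <- c(planted, list(tibble(
            fiber_id = fid, class = "PIC", start = as.integer(s),
            end = as.integer(s + pr$pic_size[k]), element = paste0("prom", k))))
        }
      }
      if (!is.null(config$polIII)) {
        p3 <- config$polIII
        cov3 <- which(p3$position - 200 >= fstart & p3$position + 300 < fend)
        for (k in cov3) {
          if (runif(1) < p3$p_footprint[k]) {
            up_start <- tss_absolute(-p3$upstream_offset[k], p3$position[k],
                                     p3$strand[k])
            s <- if (p3$strand[k] == "+") up_start else
              up_start - p3$footprint_size[k] + 1L
            planted <- c(planted, list(tibble(
              fiber_id = fid, class = "polIII", start = as.integer(s),
              end = as.integer(s + p3$footprint_size[k]),
              element = paste0("polIII", k))))
          }
        }
      }

      # nucleosome array phased off the nearest covered promoter's +1
      if (length(covered) > 0) {
        k <- covered[which.min(abs(pr$position[covered] - (fstart + fend) / 2))]
        shift <- if (ppp[k]) pr$plus1_shift_ppp[k] else 0
        plus1_rel <- round(rnorm(1, pr$plus1_mean[k] + shift, pr$plus1_sd[k]))
        anchor <- tss_absolute(plus1_rel, pr$position[k], pr$strand[k])
        if (pr$strand[k] == "-") anchor <- anchor - config$nucleosome_size + 1L
        keepout <- c(planted, list(tibble(
          fiber_id = fid, class = "keepout",
          start = as.integer(min(pr$position[k] - 100, anchor) ),
          end = as.integer(max(pr$position[k] + 100, anchor)),
          element = paste0("prom", k))))
      } else {
        anchor <- fstart + sample.int(config$nucleosome_repeat, 1) - 1L
        keepout <- planted
      }
      slot_starts <- sort(unique(c(
        seq(anchor, fend, by = config$nucleosome_repeat),
        seq(anchor, fstart - config$nucleosome_size,
            by = -config$nucleosome_repeat)
      )))
      slot_starts <- slot_starts[slot_starts >= fstart &
                                   slot_starts + config$nucleosome_size <= fend]
      occ <- runif(length(slot_starts)) < config$nucleosome_occupancy
      slot_starts <- slot_starts[occ]
      if (length(keepout) > 0 && length(slot_starts) > 0) {
        # planted PPP/PIC/Pol III footprints displace colliding nucleosomes
        # and keep a minimal 15 bp linker so runs stay separable
        ko <- bind_rows(keepout)
        linker <- 15L
        collide <- vapply(slot_starts, function(s)
          any(s < ko$end + linker &
                s + config$nucleosome_size > ko$start - linker), logical(1))
        n_displaced <- n_displaced + sum(collide)
        slot_starts <- slot_starts[!collide]
      }
      if (length(slot_starts) > 0) {
        planted <- c(planted, list(tibble(
          fiber_id = fid, class = "nucleosome", start = as.integer(slot_starts),
          end = as.integer(slot_starts + config$nucleosome_size),
          element = NA_character_)))
      }
      fp <- if (length(planted) > 0) arrange(bind_rows(planted), .data$start)
            else tibble(fiber_id = character(), class = character(),
                        start = integer(), end = integer(), element = character())
      fp_truth[[i]] <- fp

      sites <- fstart + which(runif(fend - fstart) < config$a_density) - 1L
      inside <- rep(FALSE, length(sites))
      if (nrow(fp) > 0 && length(sites) > 0) {
        for (r in seq_len(nrow(fp)))
          inside <- inside | (sites >= fp$start[r] & sites < fp$end[r])
      }
      meth <- runif(length(sites)) < ifelse(inside, config$p_inacc, config$p_acc)
      rows[[i]] <- tibble(
        fiber_id = fid, chrom = config$chrom, start = as.integer(fstart),
        end = as.integer(fend), strand = "+",
        a_sites = list(as.integer(sites)), methylated = list(meth),
        dataset = NA_character_
      )
      occ_truth[[i]] <- tibble(
        fiber_id = fid, promoter = paste0("prom", seq_len(nrow(pr))),
        covered = seq_len(nrow(pr)) %in% covered, ppp = ppp, pic = pic
      )
    }
    list(
      fibers = validate_fibers(bind_rows(rows)),
      truth = list(footprints = bind_rows(fp_truth),
                   occupancy = bind_rows(occ_truth),
                   n_displaced = n_displaced, config = config)
    )
  })
}

#' Simulate calibration control fiber sets
#'
#' The positive control emulates methyltransferase-treated dechromatinized
#' genomic DNA (every adenine accessible); the negative control emulates
#' untreated DNA (every call a false positive). In sequence mode
#' (`reference` supplied) adenine sites sit at the reference's A/T positions
#' and per-context rates can be supplied via `context_rates` (tibble:
#' context, p_acc, p_inacc; contexts canonicalized to the adenine strand).
#'
#' @param config a [sim_config()] (supplies lengths, density and global
#'   rates).
#' @param n_fibers fibers per control set (default `config$n_fibers`).
#' @param reference optional reference sequences for sequence mode.
#' @param context_rates optional per-context rate tibble (sequence mode).
#' @param context_width context width for `context_rates` lookup.
#' @return list with `positive` and `negative` fiber tibbles.
#' @export
simulate_controls <- function(config, n_fibers = config$n_fibers,
                              reference = NULL, context_rates = NULL,
                              context_width = 7L) {
  with_seed(config$seed + 1L, {
    mk <- function(which_state, tag) {
      rows <- vector("list", n_fibers)
      for (i in seq_len(n_fibers)) {
        len <- max(2000, round(rnorm(1, config$read_mean, config$read_sd)))
        if (is.null(reference)) {
          G <- config$genome_length
          fstart <- sample.int(max(1L, G - len + 1L), 1) - 1L
          fend <- min(G, fstart + len)
          sites <- fstart + which(runif(fend - fstart) < config$a_density) - 1L
          p <- if (which_state == "acc") config$p_acc else config$p_inacc
          pv <- rep(p, length(sites))
          chrom <- config$chrom
        } else {
          ref <- as_reference(reference)
          chrom <- sample(names(ref), 1)
          G <- nchar(ref[[chrom]])
          len <- min(len, G)
          fstart <- sample.int(max(1L, G - len + 1L), 1) - 1L
          fend <- min(G, fstart + len)
          bases <- strsplit(substring(ref[[chrom]], fstart + 1L, fend), "")[[1]]
          rel <- which(bases %in% c("A", "T"))
          sites <- fstart + rel - 1L
          strand <- ifelse(bases[rel] == "A", "+", "-")
          col <- if (which_state == "acc") "p_acc" else "p_inacc"
          pv <- rep(if (which_state == "acc") config$p_acc else config$p_inacc,
                    length(sites))
          if (!is.null(context_rates)) {
            ctx <- context_at(reference, rep(chrom, length(sites)), sites,
                              strand, width = context_width)
            m <- match(ctx, context_rates$context)
            pv[!is.na(m)] <- context_rates[[col]][m[!is.na(m)]]
          }
        }
        rows[[i]] <- tibble(
          fiber_id = sprintf("%s%05d", tag, i), chrom = chrom,
          start = as.integer(fstart), end = as.integer(fend), strand = "+",
          a_sites = list(as.integer(sites)),
          methylated = list(runif(length(sites)) < pv),
          dataset = tag
        )
      }
      validate_fibers(bind_rows(rows))
    }
    list(positive = mk("acc", "pos"), negative = mk("inacc", "neg"))
  })
}

#' Simulate nascent-RNA signal tracks consistent with planted footprints
#'
#' CAGE-seq signal is placed at each promoter TSS and PRO-seq signal at the
#' TSS plus the configured pause offset; peak heights are 9 plus the number
#' of fibers on which the corresponding footprint was planted, so active
#' promoters clear the 10-read peak floor and promoters with zero planted
#' occupancy stay below it. START-seq signal is placed at promoter TSSs and
#' at configured enhancer eRNA positions.
#'
#' @param sim result of [simulate_fibers()].
#' @return list of track tibbles: `pro`, `cage`, `start`.
#' @export
simulate_tracks <- function(sim) {
  config <- sim$truth$config
  pr <- config$promoters
  occ <- sim$truth$occupancy
  counts <- occ |>
    filter(.data$covered) |>
    group_by(.data$promoter) |>
    summarise(n_ppp = sum(.data$ppp), n_pic = sum(.data$pic), .groups = "drop")
  m <- match(paste0("prom", seq_len(nrow(pr))), counts$promoter)
  n_ppp <- ifelse(is.na(m), 0L, counts$n_ppp[m])
  n_pic <- ifelse(is.na(m), 0L, counts$n_pic[m])
  height <- function(n) ifelse(n > 0, 9 + n, 0)
  pro_pos <- tss_absolute(pr$pause_offset, pr$position, pr$strand)
  pro <- signal_track(config$chrom, pro_pos, height(n_ppp))
  cage <- signal_track(config$chrom, pr$position, height(n_pic))
  st_chrom <- rep(config$chrom, nrow(pr))
  st_pos <- pr$position
  st_score <- height(pmax(n_ppp, n_pic))
  if (!is.null(config$enhancers)) {
    en <- config$enhancers
    st_chrom <- c(st_chrom, rep(config$chrom, nrow(en)))
    st_pos <- c(st_pos, en$position + en$erna_offset)
    st_score <- c(st_score, en$height)
  }
  list(pro = pro, cage = cage, start = signal_track(st_chrom, st_pos, st_score))
}

#' Generate a random reference sequence
#'
#' @param length_bp contig length.
#' @param gc GC fraction (default 0.42, fly-like).
#' @param seed integer seed.
#' @param chrom contig name.
#' @return named character vector of length 1.
#' @export
random_reference <- function(length_bp, gc = 0.42, seed, chrom = "chrS") {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    setNames(paste(sample(names(p), length_bp, replace = TRUE, prob = p),
                   collapse = ""), chrom)
  })
}
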