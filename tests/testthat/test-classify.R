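test_that("promoter footprint classification matches the golden table", {
  fx <- golden_fixture()
  got_d <- classify_promoter_footprints(fx$fp, fx$peaks, fx$genes)
  expect_equal(got_d$label, fx$cases$exp_default,
               info = paste(fx$cases$case, collapse = ","))
  got_s <- classify_promoter_footprints(fx$fp, fx$peaks, fx$genes, strict = TRUE)
  expect_equal(got_s$label, fx$cases$exp_strict)
})

test_that("classification is deterministic and order-invariant", {
  fx <- golden_fixture()
  shuffle <- sample(nrow(fx$fp))
  got <- classify_promoter_footprints(fx$fp[shuffle, ], fx$peaks, fx$genes)
  expect_equal(got$label, fx$cases$exp_default[shuffle])
  # PPP and PIC can never both apply: their size ranges are disjoint
  rules <- classification_rules()
  expect_lte(rules$ppp_size[2], rules$pic_size[1])
})

test_that("promoter accessibility distinguishes inaccessible from not-evaluable", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chrT", tss = 10000L,
                         gene_end = 15000L, strand = "+", gene_class = "polII")
  fb <- fibers(c("spanning", "nuc", "small", "short"),
               rep("chrT", 4), c(5000L, 5000L, 5000L, 10050L),
               c(15000L, 15000L, 15000L, 15000L), "+",
               a_sites = list(6000L, 6000L, 6000L, 10060L),
               methylated = list(TRUE, TRUE, TRUE, TRUE))
  fp <- tibble::tibble(
    fiber_id = c("nuc", "small", "spanning"), chrom = "chrT", strand = ".",
    start = c(9950L, 9970L, 9800L), end = c(10097L, 10050L, 9895L),
    size = c(147L, 80L, 95L), n_sites = 5L, mean_posterior = 0.9,
    label = "unknown"
  )
  acc <- promoter_accessibility(fp, fb, gene)
  get <- function(id) acc$accessible[acc$fiber_id == id]
  expect_false(get("nuc"))        # 147 bp footprint covering the TSS
  expect_true(get("small"))       # 80 bp over the TSS is not nucleosome-sized
  expect_true(get("spanning"))    # 95 bp footprint ending upstream of TSS-10
  expect_true(is.na(get("short")))  # fiber does not span the window
  expect_false(acc$evaluable[acc$fiber_id == "short"])
})

test_that("elongating footprints respect the TSS exclusion zone", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chrT", tss = 10000L,
                          gene_end = 30000L, strand = "+", gene_class = "polII")
  all_tss <- tibble::tibble(chrom = "chrT", tss = 10000L)
  fb <- fibers("f1", "chrT", 9000L, 29000L, "+",
               a_sites = list(9500L), methylated = list(TRUE))
  fp <- tibble::tibble(
    fiber_id = "f1", chrom = "chrT", strand = ".",
    start = c(12000L, 10100L, 15000L, 20000L, 9400L),
    end = c(12050L, 10150L, 15050L, 20050L, 9450L),
    size = 50L, n_sites = 10L, mean_posterior = 0.9, label = "unknown"
  )
  res <- find_elongating(fp, fb, genes, all_tss)
  lab <- res$footprints$label
  expect_equal(lab[1], "elongating")   # 2 kb into the body
  expect_equal(lab[2], "unknown")      # TSS+100: inside the exclusion zone
  expect_equal(lab[3], "elongating")
  expect_equal(lab[4], "elongating")
  expect_equal(lab[5], "unknown")      # upstream of the gene, intergenic
  # 3 qualifying footprints over ~18.7 kb of covered body
  expect_equal(res$stats$n_elongating, 3)
  expect_equal(res$stats$gene_body_bp, 29000 - 10301)
  expect_equal(res$stats$density_per_kb,
               3 / (29000 - 10301) * 1000, tolerance = 1e-12)
})

test_that("elongating density arithmetic matches the stated example", {
  # 3 qualifying footprints over 20 kb of covered gene body = 1.5 per 10 kb
  expect_equal(3 / 20000 * 1000 * 10, 1.5)
})

test_that("Pol III classification follows size, offset and box clauses", {
  trna <- tibble::tibble(gene_id = "t1", chrom = "chrT", tss = 5000L,
                         gene_end = 5080L, strand = "+", gene_class = "tRNA")
  r5s <- dplyr::mutate(trna, gene_id = "s1", gene_class = "rRNA5S")
  boxes <- tibble::tibble(gene_id = c("t1", "t1", "s1"), box = c("A", "B", "A"),
                          start = c(5010L, 5052L, 5010L),
                          end = c(5021L, 5063L, 5021L))
  fb <- fibers("f1", "chrT", 4000L, 6000L, "+",
               a_sites = list(4500L), methylated = list(TRUE))
  mk_fp <- function(start, size) tibble::tibble(
    fiber_id = "f1", chrom = "chrT", strand = ".", start = start,
    end = start + size, size = size, n_sites = 5L, mean_posterior = 0.9,
    label = "unknown")
  call1 <- function(fp, gene) {
    classify_polIII(fp, fb, gene, boxes)$polIII[1]
  }
  # upstream offset boundaries at size 100
  expect_false(call1(mk_fp(5000L - 44L, 100L), trna))
  expect_true(call1(mk_fp(5000L - 45L, 100L), trna))
  expect_true(call1(mk_fp(5000L - 55L, 100L), trna))
  expect_false(call1(mk_fp(5000L - 56L, 100L), trna))
  # size boundaries at offset 50
  expect_true(call1(mk_fp(4950L, 30L), trna))
  expect_true(call1(mk_fp(4950L, 140L), trna))
  expect_false(call1(mk_fp(4950L, 141L), trna))
  # the 5S cap is 160 bp
  expect_true(call1(mk_fp(4950L, 150L), r5s))
  expect_true(call1(mk_fp(4950L, 160L), r5s))
  expect_false(call1(mk_fp(4950L, 161L), r5s))
  expect_false(call1(mk_fp(4950L, 150L), trna))
  # box clause: < 90 bp footprint at the B-box alone
  expect_true(call1(mk_fp(5050L, 70L), trna))
  expect_false(call1(mk_fp(5050L, 90L), trna))
  # a footprint away from boxes and offset window
  expect_false(call1(mk_fp(5200L, 70L), trna))
})

test_that("transcription frequency is the fraction of positive fibers", {
  mk <- function(n, k) tibble::tibble(
    fiber_id = paste0("f", 1:n), gene_id = "t1", evaluable = TRUE,
    polIII = seq_len(n) <= k)
  expect_equal(transcription_frequency(mk(100, 40))$frequency, 0.4)
  expect_equal(transcription_frequency(mk(50, 0))$frequency, 0)
  expect_equal(transcription_frequency(mk(30, 30))$frequency, 1)
})

test_that("codon correlation matches the covariance-formula oracle", {
  set.seed(7)
  n_fam <- 20
  freq <- runif(n_fam, 0.001, 0.04)
  copies <- sample(1:3, n_fam, replace = TRUE)
  # per-gene scores sum to 10 * codon frequency within each family
  scores <- tibble::tibble(
    family = rep(paste0("fam", 1:n_fam), copies),
    score = rep(freq * 10 / copies, copies),
    coverage = 100
  )
  scores$gene_id <- paste0("t", seq_len(nrow(scores)))
  codons <- tibble::tibble(family = paste0("fam", 1:n_fam), frequency = freq)
  res <- codon_correlation(scores, codons)
  expect_equal(res$r_scores, 1, tolerance = 1e-12)
  expect_equal(res$n_families, n_fam)
  # r agrees with the direct covariance formula
  expect_equal(res$r_scores, pearson_oracle(freq * 10, freq), tolerance = 1e-12)
  expect_equal(res$r_counts, pearson_oracle(copies, freq), tolerance = 1e-12)
  # permuted scores decorrelate in expectation (equal family sizes, so the
  # permutation null is centered at zero)
  eq <- tibble::tibble(
    gene_id = paste0("e", 1:(2 * n_fam)),
    family = rep(paste0("fam", 1:n_fam), each = 2),
    score = rep(freq * 5, each = 2), coverage = 100
  )
  rs <- replicate(100, {
    scr <- eq; scr$score <- sample(scr$score)
    codon_correlation(scr, codons)$r_scores
  })
  expect_lt(abs(mean(rs)), 0.15)
  # extreme-coverage members disqualify their whole family
  scr <- scores
  scr$coverage[1] <- 1e6
  res2 <- codon_correlation(scr, codons)
  expect_equal(res2$n_families, n_fam - 1)
})
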