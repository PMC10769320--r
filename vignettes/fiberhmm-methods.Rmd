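---
title: "Calling single-molecule chromatin footprints with fiberhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling single-molecule chromatin footprints with fiberhmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberhmm)
library(dplyr)
```

## The measurement and the model

Fiber-seq-style assays stencil protein occupancy onto DNA: a nonspecific
adenine methyltransferase methylates every adenine it can reach, so on a
single long read the methylated adenines mark accessible DNA and runs of
unmethylated adenines mark protein-occluded DNA — nucleosomes, the
preinitiation complex (PIC), promoter-proximally paused RNA polymerase II
(PPP), TFIIIB/TFIIIC at Pol III genes, and smaller factors. Each read is one
chromatin fiber; the analytical task is to segment its adenine sites into
*accessible* and *inaccessible* stretches despite two noise sources: the
methyltransferase and base-caller miss accessible adenines (false negatives
of accessibility), and occluded adenines are sometimes called methylated
(false positives).

`fiberhmm` models each fiber as a two-state hidden Markov model over the
*chain of adenine sites* (not base pairs): hidden state 1 = accessible,
state 2 = inaccessible; the observation at each site is its binary
methylation call. Emission probabilities are *fixed, measured quantities*,
not fitted parameters:

* `p_acc(c)` — probability a methylatable adenine in context `c` is called
  methylated when accessible, estimated from a fully dechromatinized,
  methyltransferase-treated genomic DNA control (everything accessible);
* `p_inacc(c)` — probability of a methylation call when inaccessible,
  estimated from untreated DNA (every call a false positive).

The context `c` is the adenine's ±3 nt sequence on the adenine-bearing
strand (reverse-complemented for adenines on the reverse strand, so the
center is always `A`); this absorbs sequence preferences of the enzyme and
the caller. Rates are Laplace-smoothed, `(k + 1)/(n + 2)` by default, so no
emission is ever exactly 0 or 1 — a zero would make entire state paths
impossible and Baum-Welch ill-defined. Contexts never observed in a control,
containing non-ACGT bases, or within 3 bp of a contig edge fall back to the
control's global rate. Calibration refuses to proceed when the positive
control's global rate does not exceed the negative's, which indicates
swapped or degenerate controls.

Only the start vector and the 2×2 transition matrix are trained, by
Baum-Welch EM on a subsample of reads (default 1000, drawn in equal
proportions from the available dataset tags), restarted 20 times from
Dirichlet(1,1) draws with the highest-likelihood restart kept. Training
read ids are recorded in the fitted object so downstream analyses can
exclude them. Decoding is Viterbi; maximal runs of the inaccessible state
become footprints spanning `[first a-site of the run, last a-site + 1)`,
each annotated with its mean forward–backward posterior. Ties in the
Viterbi recursion break toward the accessible state, which is the
conservative direction for footprint calling.

Two modeling choices deserve emphasis. First, transitions are homogeneous
in *site index*: the genomic distance between consecutive adenine sites is
not modeled. This matches the plain-HMM design and is adequate at fly-like
A/T density (an adenine on one strand or the other every ~2 bp); at very
low density a distance-aware (semi-Markov) variant would be preferable and
is deliberately out of scope. Second, emissions are frozen during EM: the
controls measure them directly, and freeing them would let the model trade
emission noise against segment structure.

## Boundary resolution: what is knowable

A footprint boundary is only observable through the adenine lattice, so
decoded boundaries are anchored to observed sites. Moreover, when the edge
adenine of a true footprint is a methylation false positive (probability
`p_inacc` = 0.04 in the default conditions) the evidence pattern at the
edge — methylated, then one unmethylated site — favors truncating the call
by two sites for *any* decoder: the likelihood ratio for exclusion over
inclusion is `e^0.85 ≈ 2.3`, independent of the transition probabilities.
This puts a ceiling of roughly 96% on per-boundary site-resolution accuracy
and ~88–89% on the fraction of footprints with *both* boundaries inside one
inter-adenine gap. The validation suite therefore scores recovery as (a)
detection of planted nucleosome footprints by majority overlap (measured
≈ 1.00) and (b) the per-boundary rate of landing within one local
inter-adenine spacing of the planted boundary's anchor site (measured
≈ 0.94); the stricter conjunctive number is also reported by the acceptance
script (`footprint_recovery_strict`, ≈ 0.88, at its theoretical ceiling).

## Classifying footprints

Footprint classes follow size, position and peak-coincidence rules
(`classification_rules()`):

| class | size (bp) | position rule |
|---|---|---|
| PPP | [40, 60) | primary PRO-seq peak in the central 70% of the footprint (50% in strict mode) and 0–100 bp downstream of the CAGE-adjusted TSS |
| PIC | [60, 80) | primary CAGE-seq peak in the central 70% and within ±50 bp of the TSS |
| nucleosome | > 90 | — |
| single nucleosome | [90, 200] | predicate used by ±1-nucleosome analyses |
| elongating Pol II | [40, 60) | in a gene body, > 300 bp from every annotated or eRNA TSS |
| Pol III (tRNA) | [30, 140] | starts 45–55 bp upstream of the TSS, or < 90 bp over the A-/B-box alone |
| Pol III (5S) | [30, 160] | same, with the larger cap |

The published size ranges touch at 60 and 80 bp; we use half-open intervals
so the partition is deterministic, and a size of exactly 90 satisfies the
single-nucleosome predicate but not the strict `> 90` nucleosome label —
both stated bounds are honored literally. Footprints under 40 bp stay
`unknown` (transcription-factor-scale footprints are not classified). When
a gene lacks a CAGE primary peak the annotation TSS anchors the PPP window.
The strict core-overlap mode applies to PPP only, where false positives at
low-pause-index genes are the documented concern.

Peak calling scans a sliding 20 bp window over −50..+50 bp (CAGE/START) or
0..+100 bp (PRO) around the TSS; each window position contributes its
per-base maximum (ties resolve toward the TSS), candidates need ≥ 10 reads,
the strongest is primary, and any other candidate above one tenth of the
primary is discarded — or, with `strict_primary`, flags the gene for
exclusion (both readings of the 10-fold rule are implemented; discard-peak
is the default). The pause index is the ratio of promoter (−100..+300)
PRO-seq density to gene-body (+300..end) density, both per-bp, making it
unit-free; genes bin as high (PI ≥ 100), mid (100 > PI ≥ 10), low (PI < 10).

## Architecture and coordination statistics

Pause-associated nucleosome analyses compare fibers with and without a PPP
footprint at each gene after balancing counts per gene by subsampling
(`subsample_matched()`), repeated over ≥ 50 seeds (`resample_stat()`) so
conclusions do not ride on one draw. Nucleosome positions are segmented
with a 1-D Gaussian mixture fitted by EM (k-means initialization, variance
floored at 1e-3 bp, non-convergence after 500 iterations is an error);
footprints join a component only inside its 95% interval (mean ± 1.96 sd).
The per-gene ±1-nucleosome tests use a two-sided Wilcoxon rank-sum computed
by exact enumeration whenever `choose(n+m, min(n,m))` is small (covering
all groups of ≤ 8), falling back to the tie-corrected normal approximation
with continuity correction — identical groups correctly give p = 1 instead
of the 0/0 the textbook variance formula produces under total ties. The
per-read test bootstraps the no-PPP feature distribution (1000 percentile
resamples) and flags PPP reads outside the 95% interval. A fiber's +1
nucleosome is its first single-nucleosome footprint starting at or after
the TSS (strand-aware); "shifted" means starting 70–150 bp downstream,
inclusive.

Single-fiber co-occupancy uses a 2×2 table per element pair — feature
present/absent at each element on fibers spanning both, optionally
restricted to fibers with both promoters accessible (no > 90 bp footprint
within ±10 bp of either TSS). `fisher_exact()` reports the cross-product
odds ratio with Haldane–Anscombe +0.5 applied only when a cell is zero,
and the two-sided p-value as the sum of hypergeometric probabilities no
larger than the observed table's (the correction never touches the p-value).
Pairs are binned by distance so each bin holds a roughly equal number of
simultaneous events (greedy cumulative partition); per-locus coordination
calls a pair significant only when OR > 1 *and* p < 0.05, so
anti-coordinated pairs never count. The TAD/insulator comparison samples
pairs from both groups to a shared 250 bp distance histogram, 10 000 times
by default, giving percentile intervals for each group's pooled OR and an
empirical p-value for their difference. Raw Fisher p-values are reported
per bin, as is conventional for these analyses; no multiplicity correction
is applied across bins.

## The synthetic-fiber generator

Because the assay's raw data cannot be bundled, every analysis is exercised
on generated fibers with planted ground truth (`simulate_fibers()`). The
default conditions are chosen once to emulate the assay at desk scale:
15 kb mean reads (sd 2 kb), adenine-site density 0.55/bp (an A or T at
~58% of positions in an AT-rich fly genome, adenines counted on both
strands), emission pair (0.9, 0.04), 147 bp nucleosome cores on a 185 bp
repeat at 80% occupancy, PPP footprints of 50 bp centered on a PRO peak
40 bp downstream of the TSS, PIC footprints of 70 bp centered on the TSS,
and a +1 nucleosome starting at +60 ± 10 bp. Pairwise co-occupancy is
planted by drawing the two promoters' PPP indicators from the unique joint
distribution with the configured marginals and odds ratio
(`joint_from_or()`); steric exclusion, when enabled, forbids simultaneous
PPP and PIC at promoters whose PRO/CAGE peak distance is under 60 bp.
Planted promoter and Pol III footprints displace colliding nucleosomes and
keep a 15 bp minimal linker — two inaccessible runs separated by less than
a handful of methylatable adenines are physically one run, and a generator
that fused them would be testing an impossibility rather than the caller.
Sequence-free mode (uniform site density, global emission pair) is the
default for speed; sequence mode consumes a reference and per-context
rates. What the generator does *not* emulate: PacBio error models and
kinetics, mappability structure, copy-number variation, context-dependent
enzyme processivity along a fiber, and biological heterogeneity between
cells beyond the planted occupancy probabilities — so green tests certify
the inference machinery, not robustness to every artifact of real data.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to estimate each quantity
stably: 200 fibers of ≤ 12 sites against the exact path-enumeration oracle;
1000 simulated 10 kb fibers for transition-recovery (±0.02); ~4000 planted
nucleosomes for boundary statistics; 16 3-mer contexts at ≥ 10⁴
observations each for calibration convergence (±0.01; the estimator is
width-agnostic, and 4096 7-mer contexts at that depth would need ~4×10⁷
control sites); 2000-fiber replicates for odds-ratio coverage; a 600-fiber
end-to-end chain. EM stops when the log-likelihood gain drops below 1e-6
(500 iterations cap); monotonicity is asserted up to 1e-10 relative to the
likelihood scale, the observed round-off at convergence. All likelihood
arithmetic is in scaled (forward) or log (Viterbi) space.

## Known limitations

Inter-site distance is ignored by the transition model; footprints
separated by linkers shorter than ~3 methylatable sites cannot be split;
boundary placement saturates at the information limit described above;
eRNA TSS orientation is not resolved (enhancer annotations are treated as
unstranded, `+` by convention); A-box/B-box intervals are inputs, not
predicted from sequence; and the co-occupancy machinery assumes fibers are
independent draws, which long-read duplicates would violate upstream.
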