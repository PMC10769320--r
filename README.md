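# fiberhmm

Single-molecule chromatin footprint calling from m6A-marked fibers, with
the downstream statistics to ask how transcription machinery and
nucleosomes arrange themselves *on the same molecule*.

Fiber-seq-style assays treat permeabilized nuclei with a nonspecific
adenine methyltransferase and read the DNA on long single-molecule reads:
methylated adenines mark accessible DNA, and runs of unmethylated adenines
are the footprints of bound proteins. `fiberhmm` is for genomicists working
with such data (or building methods for it) who need to go from per-read
methylation calls to classified footprints and single-fiber co-occupancy
statistics without the original lab's unreleased data: every stage can be
exercised on simulated fibers with planted ground truth.

The core is a two-state HMM over each fiber's chain of adenine sites
(states *accessible*/*inaccessible*, observations the binary m6A calls).
Emissions are fixed at measured per-context rates — P(m6A | accessible)
from a methylated dechromatinized-gDNA control and P(m6A | inaccessible)
from an untreated control, each for the adenine's ±3 nt context — while
the start vector π and transition matrix A are trained by Baum–Welch
(20 restarts from Dirichlet(1,1), best likelihood wins, emissions frozen):

    P(obs, states) = π(s₁) e(o₁|s₁) ∏ₜ A(sₜ₋₁, sₜ) e(oₜ|sₜ)

Viterbi runs of the inaccessible state become footprints, which are then
classified by size and nascent-RNA peak coincidence: paused Pol II (PPP,
40–60 bp on the primary PRO-seq peak), preinitiation complex (PIC,
60–80 bp on the primary CAGE-seq peak), nucleosomes (> 90 bp), elongating
Pol II, and Pol III transcription-associated footprints at tRNA/5S genes.
On top of the calls sit the analyses: pause index and expression from
PRO-seq, transcribed-enhancer discovery from START-seq, Gaussian-mixture
nucleosome positioning with ±1-nucleosome shift statistics, and Fisher
exact co-occupancy odds ratios between element pairs on single fibers,
binned by distance or compared across TAD boundaries with distance-matched
resampling.

## A worked example

Simulate fibers over two promoters whose paused-polymerase occupancy is
coordinated (odds ratio 3), calibrate emissions from simulated controls,
train, decode, classify, and measure the planted coordination:

```r
library(fiberhmm)
library(dplyr)

cfg <- sim_config(
  n_fibers = 200, genome_length = 100000,
  promoters = tibble(position = c(40000L, 43000L), strand = "+",
                     p_ppp = 0.3, p_pic = 0),
  pair_structure = tibble(i = 1L, j = 2L, or = 3),
  seed = 1
)
sim  <- simulate_fibers(cfg)
ctrl <- simulate_controls(cfg, n_fibers = 50)

tab <- build_emission_table(ctrl$positive, ctrl$negative)
#> <emission_table> context width 7
#>   global: p(meth|accessible) = 0.8996  p(meth|inaccessible) = 0.03943

fit <- train_hmm(sim$fibers, tab, n_restarts = 5, n_reads = 200, seed = 2)
#> <hmm_params> two-state accessibility HMM
#>   start: accessible=0.9974  inaccessible=0.0026
#>   transitions:
#>               to
#> from           accessible inaccessible
#>   accessible       0.9772       0.0228
#>   inaccessible     0.0136       0.9864

fp <- decode_footprints(sim$fibers, tab, fit)
nrow(fp)
#> [1] 12946
```

The calibrated rates recover the generator's 0.9/0.04 emission pair, and
the trained diagonal (~0.98) says both states persist across many adenine
sites, as nucleosome-scale footprints require. Classification needs the
toy signal tracks and gene models:

```r
tracks <- simulate_tracks(sim)
genes <- tibble(gene_id = c("gA", "gB"), chrom = "chrS",
                tss = c(40000L, 43000L), gene_end = c(42000L, 45000L),
                strand = "+", gene_class = "polII")
peaks <- bind_rows(call_tss_peaks(tracks$pro, genes, "PRO"),
                   call_tss_peaks(tracks$cage, genes, "CAGE"))
fp <- classify_promoter_footprints(fp, peaks, genes)
count(fp, label)
#>   label          n
#> 1 PPP           16
#> 2 nucleosome 12805
#> 3 unknown      125

pairs <- promoter_pair_fibers(fp, sim$fibers, genes)
global_coordination(pairs, n_bins = 1, require_accessible = TRUE)
#>   bin d_lo d_hi n_pairs n11 n10 n01 n00  n odds_ratio p_value
#> 1   1 3000 3000       1   3   1   1   7 12         21  0.0667
```

Twelve fibers span both promoters with both promoters nucleosome-free;
paused polymerase co-occurs on three of them, an odds ratio above 1 in the
planted direction (at this depth the Fisher interval is wide — the
validation suite repeats this at 2000 fibers per bin, where the estimate
brackets the planted value tightly).

A command-line front end wraps the same functions for shell pipelines:

```sh
FH=$(Rscript -e 'cat(system.file("scripts/fiberhmm.R", package="fiberhmm"))')
Rscript $FH simulate  --out-dir sim/ --seed 7
Rscript $FH calibrate --positive sim/control_positive.bed \
                      --negative sim/control_negative.bed --out sim/emissions.tsv
Rscript $FH train     --fibers sim/fibers.bed --emissions sim/emissions.tsv \
                      --seed 7 --out sim/params.json
Rscript $FH call      --fibers sim/fibers.bed --emissions sim/emissions.tsv \
                      --params sim/params.json --out sim/footprints.bed
Rscript $FH classify  --footprints sim/footprints.bed --fibers sim/fibers.bed \
                      --pro sim/pro.bedgraph --cage sim/cage.bedgraph \
                      --genes sim/genes.bed --out sim/labeled.bed
Rscript $FH coordinate --labeled sim/labeled.bed --fibers sim/fibers.bed \
                      --genes sim/genes.bed --out sim/coord.tsv
```

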