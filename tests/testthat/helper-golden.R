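# Golden classification fixture shared by the unit and acceptance suites.
# Golden classification table: hand-constructed footprints exercising every
# boundary of the size / core-overlap / position rules, one case per contig
# so peak assignments cannot leak across cases. PRO primary at TSS+40 and
# CAGE primary at the TSS unless the case says otherwise.

golden_cases <- function() {
  # fp interval [start, end); peaks in genomic coordinates
  tibble::tribble(
    ~case,            ~fp_start, ~fp_size, ~pro_peak, ~cage_peak, ~exp_default, ~exp_strict,
    "size39_pro",       10021L,     39L,    10040L,    10000L,    "unknown",   "unknown",
    "size40_pro",       10020L,     40L,    10040L,    10000L,    "PPP",       "PPP",
    "size59_pro",       10011L,     59L,    10040L,    10000L,    "PPP",       "PPP",
    "size60_on_pro",    10010L,     60L,    10040L,    10000L,    "unknown",   "unknown",
    "size60_on_cage",    9970L,     60L,    10040L,    10000L,    "PIC",       "PIC",
    "size79_on_cage",    9961L,     79L,    10040L,    10000L,    "PIC",       "PIC",
    "size80_on_cage",    9960L,     80L,    10040L,    10000L,    "unknown",   "unknown",
    "size90",            9955L,     90L,    10040L,    10000L,    "unknown",   "unknown",
    "size91",            9955L,     91L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size140",           9930L,    140L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size141",           9930L,    141L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size150",           9925L,    150L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size160",           9920L,    160L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size161",           9920L,    161L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size200",           9900L,    200L,    10040L,    10000L,    "nucleosome","nucleosome",
    "size201",           9900L,    201L,    10040L,    10000L,    "nucleosome","nucleosome",
    # 50 bp footprint [10015, 10065); PRO peak parked at 10/26/50/74/80%
    # of the footprint length; central 70% = [10022.5, 10057.5], 50% =
    # [10027.5, 10052.5]
    "frac10",           10015L,     50L,    10020L,    10000L,    "unknown",   "unknown",
    "frac26",           10015L,     50L,    10028L,    10000L,    "PPP",       "PPP",
    "frac50",           10015L,     50L,    10040L,    10000L,    "PPP",       "PPP",
    "frac74",           10015L,     50L,    10052L,    10000L,    "PPP",       "PPP",
    "frac80",           10015L,     50L,    10055L,    10000L,    "PPP",       "unknown",
    # PRO peak outside 0..100 bp downstream of the TSS disables PPP
    "pro_peak_at_110",  10085L,     50L,    10110L,    10000L,    "unknown",   "unknown",
    # CAGE peak beyond +/-50 of the TSS disables PIC
    "cage_at_60",       10025L,     70L,    10040L,    10060L,    "unknown",   "unknown"
  )
}

golden_fixture <- function() {
  cases <- golden_cases()
  chrom <- paste0("c_", cases$case)
  fp <- tibble::tibble(
    fiber_id = "f1", chrom = chrom, strand = ".",
    start = cases$fp_start, end = cases$fp_start + cases$fp_size,
    size = cases$fp_size, n_sites = 10L, mean_posterior = 0.99,
    label = "unknown"
  )
  genes <- tibble::tibble(gene_id = paste0("g_", cases$case), chrom = chrom,
                          tss = 10000L, gene_end = 15000L, strand = "+",
                          gene_class = "polII")
  peaks <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes$gene_id, assay = "PRO",
                   primary_peak = cases$pro_peak, primary_value = 30,
                   secondary_peaks = list(integer()), adjusted_tss = 10000L,
                   strict_violation = FALSE),
    tibble::tibble(gene_id = genes$gene_id, assay = "CAGE",
                   primary_peak = cases$cage_peak, primary_value = 30,
                   secondary_peaks = list(integer()),
                   adjusted_tss = cases$cage_peak, strict_violation = FALSE)
  )
  list(cases = cases, fp = fp, genes = genes, peaks = peaks)
}

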