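# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain character-vector scans and explicit loops.

# genome_model built by hand around a given sequence; meth aligned with the
# CpGs found by an independent regex scan.
toy_model <- function(seqstr, meth = NULL, chrom = "chrT",
                      truth = NULL, genes = NULL) {
  pos <- oracle_cpg_positions(seqstr)
  if (is.null(meth)) meth <- rep(1, length(pos))
  if (length(meth) == 1) meth <- rep(meth, length(pos))
  stopifnot(length(meth) == length(pos))
  if (is.null(truth))
    truth <- data.frame(chrom = chrom, start = 0L, end = nchar(seqstr),
                        label = "BACKGROUND", stringsAsFactors = FALSE)
  structure(list(
    sequences = stats::setNames(seqstr, chrom),
    cpg = stats::setNames(list(list(pos = pos, meth = meth)), chrom),
    truth_domains = truth,
    genes = genes,
    marks = NULL,
    config = sim_config(genome_length = nchar(seqstr), seed = 0L,
                        hypo_domain_length = c(1, nchar(seqstr)))),
    class = "genome_model")
}

# 0-based CpG (C) positions by regex
oracle_cpg_positions <- function(seqstr) {
  m <- gregexpr("(?=CG)", seqstr, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# brute-force Pu-mC half-site scan over every position, both strands
oracle_half_sites <- function(seqstr, meth, thr = 0.5) {
  b <- strsplit(seqstr, "")[[1]]
  L <- length(b)
  cpg <- oracle_cpg_positions(seqstr)
  methylated <- cpg[meth >= thr]               # 0-based CpG C positions
  out <- integer(0)
  for (q in 0:(L - 1)) {                       # q: 0-based genome position
    i <- q + 1                                 # 1-based index
    # plus strand: Pu then methylated CpG C
    if (q >= 1 && b[i] == "C" && q < L - 1 && b[i + 1] == "G" &&
        (q %in% methylated) && b[i - 1] %in% c("A", "G"))
      out <- c(out, q)
    # minus strand: C at q (plus-strand G), 5' minus neighbour purine
    if (q >= 1 && b[i] == "G" && b[i - 1] == "C" &&
        ((q - 1) %in% methylated) && q + 1 <= L - 1 &&
        b[i + 1] %in% c("C", "T"))
      out <- c(out, q)
  }
  sort(out)
}

# brute-force digestion: eligible consecutive pairs -> midpoint cuts
oracle_digest <- function(seqstr, meth, min_sp = 40, max_sp = 3000,
                          thr = 0.5) {
  hs <- oracle_half_sites(seqstr, meth, thr)
  L <- nchar(seqstr)
  cuts <- integer(0)
  if (length(hs) >= 2) {
    for (j in 1:(length(hs) - 1)) {
      d <- hs[j + 1] - hs[j]
      if (d >= min_sp && d <= max_sp)
        cuts <- c(cuts, (hs[j] + hs[j + 1]) %/% 2)
    }
  }
  cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  b <- c(0, cuts, L)
  data.frame(start = b[-length(b)], end = b[-1])
}

# random test sequence with a sprinkling of CpGs, plus random binary meth
random_seq_model <- function(len, cpg_n = max(1, len %/% 50)) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  acc <- which(b[-len] == "C" & b[-1] == "G")
  if (length(acc)) b[acc + 1] <- "A"
  sites <- sort(sample(seq_len(len - 1), min(cpg_n, len - 1)))
  sites <- sites[c(TRUE, diff(sites) >= 2)]
  b[sites] <- "C"; b[sites + 1] <- "G"
  seqstr <- paste(b, collapse = "")
  pos <- oracle_cpg_positions(seqstr)
  meth <- as.numeric(stats::rbinom(length(pos), 1, 0.5))
  toy_model(seqstr, meth)
}

# small default-world simulation used by several suites
small_world <- function(seed, genome_length = 1e6, n_hypo_domains = 2,
                        hypo_domain_length = c(1e5, 2e5), n_genes = 100,
                        ...) {
  simulate_genome(sim_config(
    genome_length = genome_length, n_hypo_domains = n_hypo_domains,
    hypo_domain_length = hypo_domain_length, n_genes = n_genes,
    seed = seed, ...))
}

# probe table built by hand from fold changes (chrom grid of unit probes)
fc_grid <- function(fc, chrom = "chrT", spacing = 100L) {
  n <- length(fc)
  st <- seq(0L, by = spacing, length.out = n)
  structure(data.frame(
    id = sprintf("%s_p%06d", chrom, seq_len(n)), chrom = chrom,
    start = st, end = st + 60L,
    signal_resistant = fc, signal_total = rep(1, n),
    fold_change = fc, log2_ratio = log2(fc), stringsAsFactors = FALSE),
    spacing = spacing, footprint = 60L,
    class = c("probe_table", "data.frame"))
}

# brute-force per-window CpG count by substring scan (window-boundary CpGs
# counted by the position of their C; one extra base is scanned so a CpG
# whose G spills into the next window is still counted)
oracle_window_counts <- function(seqstr, window) {
  L <- nchar(seqstr)
  starts <- seq(0, L - 1, by = window)
  vapply(starts, function(s) {
    hi <- if (s + window < L) min(s + window + 1, L) else L
    sub <- substr(seqstr, s + 1, hi)
    n <- 0
    for (i in seq_len(nchar(sub) - 1))
      if (substr(sub, i, i) == "C" && substr(sub, i + 1, i + 1) == "G")
        n <- n + 1
    n
  }, numeric(1))
}
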