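## Array-CGH readout of the size-selected McrBC-resistant fraction.
##
## Two channels per probe: the resistant (McrBC-undigested) sample and total
## genomic DNA as reference. fold_change = signal_resistant / signal_total
## and log2_ratio = log2(fold_change); fold change > 1 indicates
## hypomethylation (the probe's neighbourhood survived digestion).

SIGNAL_EPS <- 1e-3  # signal floor; prevents infinite log ratios

#' Build an evenly spaced probe grid
#'
#' @param model a `genome_model` (or a named vector of chromosome lengths).
#' @param spacing distance between probe starts, bp.
#' @param footprint probe length, bp (Agilent-style 60-mer default).
#' @return a `probe_table` data frame with unset signals.
#' @export
make_probe_grid <- function(model, spacing, footprint = 60L) {
  lengths <- if (inherits(model, "genome_model"))
    setNames(nchar(model$sequences), names(model$sequences))
  else model
  spacing <- as.integer(spacing); footprint <- as.integer(footprint)
  if (footprint < 1 || spacing < footprint)
    stopf("make_probe_grid: need spacing >= footprint >= 1")
  out <- lapply(names(lengths), function(chrom) {
    L <- lengths[[chrom]]
    if (spacing > L)
      stopf("make_probe_grid: spacing %d exceeds %s length %d",
            spacing, chrom, L)
    st <- seq.int(0L, L - footprint, by = spacing)
    data.frame(id = sprintf("%s_p%06d", chrom, seq_along(st)),
               chrom = chrom, start = st, end = st + footprint,
               signal_resistant = NA_real_, signal_total = NA_real_,
               fold_change = NA_real_, log2_ratio = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, spacing = spacing, footprint = footprint,
            class = c("probe_table", "data.frame"))
}

#' Simulate two-channel probe signals from a resistant-fragment set
#'
#' `signal_total` is 1 for every probe (uniform genomic representation).
#' `signal_resistant` is the fraction of the probe footprint covered by
#' size-selected resistant fragments, floored at a small epsilon, times
#' multiplicative lognormal noise (`sd` of the log = `noise_sd`).
#'
#' @param grid a `probe_table`.
#' @param resistant a `fragment_set` (after [size_select()]).
#' @param noise_sd lognormal noise sd; 0 gives a fully deterministic readout.
#' @param seed RNG seed for the noise draw.
#' @return the `probe_table` with signals and ratios filled.
#' @export
simulate_signals <- function(grid, resistant, noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(grid, "probe_table"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stopf("simulate_signals: noise_sd must be >= 0")
  cov <- numeric(nrow(grid))
  for (chrom in unique(grid$chrom)) {
    gi <- which(grid$chrom == chrom)
    fr <- resistant[resistant$chrom == chrom, , drop = FALSE]
    if (nrow(fr) == 0) next
    pr <- as_iranges0(grid$start[gi], grid$end[gi])
    fx <- IRanges::reduce(as_iranges0(fr$start, fr$end))
    ov <- IRanges::findOverlaps(pr, fx)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      pr[S4Vectors::queryHits(ov)], fx[S4Vectors::subjectHits(ov)]))
    covered <- tapply(w, S4Vectors::queryHits(ov), sum)
    cov[gi[as.integer(names(covered))]] <- as.numeric(covered)
  }
  frac <- cov / (grid$end - grid$start)
  noise <- with_seed(seed, exp(rnorm(nrow(grid), 0, noise_sd)))
  grid$signal_total <- rep(1, nrow(grid))
  grid$signal_resistant <- pmax(frac, SIGNAL_EPS) * noise
  recompute_ratios(grid)
}

#' Median normalization of the two channels
#'
#' Rescales `signal_resistant` so that its median across all probes equals
#' the median of `signal_total` (the Cy3/Cy5 intensity normalization used to
#' compare samples), then recomputes fold changes and log2 ratios. The
#' operation is idempotent and invariant to rescaling either channel by a
#' positive constant.
#'
#' @param grid a `probe_table` with signals filled.
#' @return normalized `probe_table`.
#' @export
normalize_probes <- function(grid) {
  stopifnot(inherits(grid, "probe_table"))
  if (any(is.na(grid$signal_resistant)) || any(is.na(grid$signal_total)))
    stopf("normalize_probes: signals are unset")
  med_r <- median(grid$signal_resistant)
  med_t <- median(grid$signal_total)
  if (med_r <= 0 || med_t <= 0)
    stopf("normalize_probes: channel median is zero; cannot normalize")
  grid$signal_resistant <- grid$signal_resistant * (med_t / med_r)
  recompute_ratios(grid)
}

recompute_ratios <- function(grid) {
  grid$fold_change <- grid$signal_resistant / grid$signal_total
  grid$log2_ratio <- log2(grid$fold_change)
  grid
}
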