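## In-silico bisulfite conversion and per-CpG methylation calling — the
## validation arm of the pipeline. Reads are born aligned (true coordinates);
## mapping is out of scope. Each read is one molecule: methylation at every
## CpG it covers is sampled once per molecule from the model's meth_state, so
## a read and its mate-strand counterpart at a shared CpG are consistent.

#' Bisulfite-convert one template molecule
#'
#' Every cytosine outside CpG context converts to thymine with probability
#' `efficiency`; a CpG-context cytosine converts only if the molecule is
#' unmethylated at that CpG (sampled Bernoulli(`meth_state`) per call).
#'
#' @param sequence template sequence (plus-strand orientation string).
#' @param cpg_pos 0-based positions (relative to `sequence`) of CpG-context
#'   cytosines on this template.
#' @param meth_state per-CpG methylation probabilities aligned with
#'   `cpg_pos`.
#' @param efficiency conversion efficiency for unmethylated cytosines
#'   (default 1).
#' @param seed optional RNG seed.
#' @return converted sequence string.
#' @export
bisulfite_convert <- function(sequence, cpg_pos, meth_state, efficiency = 1,
                              seed = NULL) {
  stopifnot(length(cpg_pos) == length(meth_state))
  with_seed(seed, {
    ch <- strsplit(sequence, "")[[1]]
    is_c <- ch == "C"
    cpg_idx <- cpg_pos + 1L
    meth_draw <- rbinom(length(cpg_idx), 1L, meth_state) == 1L
    ## unmethylated CpG cytosines convert like any other C
    convertible <- is_c
    convertible[cpg_idx[meth_draw]] <- FALSE
    conv <- which(convertible)
    if (efficiency < 1)
      conv <- conv[runif(length(conv)) < efficiency]
    ch[conv] <- "T"
    paste(ch, collapse = "")
  })
}

#' Simulate bisulfite reads over a region
#'
#' Read start positions are uniform over the region; the expected per-base
#' coverage is `coverage` within Poisson error. Minus-strand reads are
#' reverse-complemented templates converted on their own strand.
#'
#' @param model a `genome_model`.
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @param coverage target fold coverage.
#' @param read_len read length in bp (default 100).
#' @param efficiency conversion efficiency.
#' @param seed RNG seed.
#' @return data frame (`chrom`, `start`, `length`, `strand`, `seq`) of
#'   converted reads.
#' @export
simulate_bisreads <- function(model, chrom, start, end, coverage,
                              read_len = 100L, efficiency = 1, seed = 1L) {
  stopifnot(inherits(model, "genome_model"), chrom %in% names(model$cpg))
  L <- nchar(model$sequences[[chrom]])
  if (start < 0 || end > L || end <= start)
    stopf("simulate_bisreads: region outside %s bounds", chrom)
  if (end - start < read_len)
    stopf("simulate_bisreads: region shorter than read length")
  n <- round(coverage * (end - start) / read_len)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      length = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  x <- model$cpg[[chrom]]
  with_seed(seed, {
    rs <- floor(runif(n, start, end - read_len + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- rs[i]; e <- s + read_len
      tmpl <- substring(model$sequences[[chrom]], s + 1L, e)
      sel <- which(x$pos >= s - 1L & x$pos < e)  # CpGs touching the read
      if (strand[i] == "+") {
        ## plus template: CpG C at genome pos p -> read offset p - s
        keep <- x$pos[sel] >= s
        seqs[i] <- bisulfite_convert(tmpl, x$pos[sel][keep] - s,
                                     x$meth[sel][keep], efficiency)
      } else {
        ## minus template: CpG C at genome pos p+1 -> 5'->3' minus offset
        ## (e - 1) - (p + 1)
        rc <- revcomp(tmpl)
        q <- x$pos[sel] + 1L
        keep <- q >= s & q < e
        seqs[i] <- bisulfite_convert(rc, (e - 1L) - q[keep],
                                     x$meth[sel][keep], efficiency)
      }
    }
    data.frame(chrom = chrom, start = as.integer(rs), length = read_len,
               strand = strand, seq = seqs, stringsAsFactors = FALSE)
  })
}

#' Per-CpG methylation calls from bisulfite reads
#'
#' Tallies C (methylated) versus T (converted, unmethylated) evidence at each
#' CpG from every overlapping read; minus-strand reads report the
#' complementary CpG cytosine at position + 1.
#'
#' @param reads output of [simulate_bisreads()].
#' @param cpg_positions 0-based CpG (C) positions to call.
#' @param min_coverage sites with fewer informative reads are flagged
#'   low-coverage (default 5).
#' @return data frame (`chrom`, `pos`, `n_C`, `n_T`, `coverage`,
#'   `meth_fraction`, `low_coverage`).
#' @export
call_methylation <- function(reads, cpg_positions, min_coverage = 5L) {
  n_C <- integer(length(cpg_positions))
  n_T <- integer(length(cpg_positions))
  if (nrow(reads) > 0 && length(cpg_positions) > 0) {
    rstart <- reads$start; rend <- reads$start + reads$length
    for (k in seq_along(cpg_positions)) {
      p <- cpg_positions[k]
      ## plus reads read the C at p; minus reads the complementary C at p+1
      tgt <- ifelse(reads$strand == "+", p, p + 1L)
      cov <- which(tgt >= rstart & tgt < rend)
      for (i in cov) {
        off <- if (reads$strand[i] == "+") tgt[i] - rstart[i]
               else (rend[i] - 1L) - tgt[i]
        base <- substring(reads$seq[i], off + 1L, off + 1L)
        if (base == "C") n_C[k] <- n_C[k] + 1L
        else if (base == "T") n_T[k] <- n_T[k] + 1L
      }
    }
  }
  cov <- n_C + n_T
  chrom <- if (nrow(reads) > 0) reads$chrom[1] else NA_character_
  data.frame(chrom = chrom, pos = cpg_positions, n_C = n_C, n_T = n_T,
             coverage = cov,
             meth_fraction = ifelse(cov > 0, n_C / cov, NA_real_),
             low_coverage = cov < min_coverage, stringsAsFactors = FALSE)
}

#' Concordance between bisulfite calls and domain calls
#'
#' @param calls output of [call_methylation()].
#' @param domains `domain_calls` (or truth domains with HYPO labels).
#' @param cut binarization threshold on `meth_fraction` (default 0.5).
#' @return list: mean methylation inside HYPO domains and outside, and
#'   `concordance`, the fraction of callable sites whose binarized state
#'   matches the domain expectation (unmethylated inside HYPO, methylated
#'   outside).
#' @export
bis_validate_domains <- function(calls, domains, cut = 0.5) {
  hy <- domains[domains$label == "HYPO", , drop = FALSE]
  callable <- !is.na(calls$meth_fraction)
  in_hypo <- vapply(seq_len(nrow(calls)), function(i)
    any(hy$chrom == calls$chrom[i] & calls$pos[i] >= hy$start &
          calls$pos[i] < hy$end), logical(1))
  mf <- calls$meth_fraction
  expected_meth <- !in_hypo
  agree <- (mf >= cut) == expected_meth
  list(
    n_sites = sum(callable),
    mean_meth_hypo = if (any(callable & in_hypo))
      mean(mf[callable & in_hypo]) else NA_real_,
    mean_meth_outside = if (any(callable & !in_hypo))
      mean(mf[callable & !in_hypo]) else NA_real_,
    concordance = if (any(callable)) mean(agree[callable]) else NA_real_)
}

#' Write bisulfite reads as FASTQ
#'
#' Fixed quality string (no quality model is simulated).
#'
#' @param reads read table from [simulate_bisreads()].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", if (nrow(reads)) reads$length[1] else 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(sprintf("@read%06d %s:%d-%d(%s)", i, reads$chrom[i],
                         reads$start[i], reads$start[i] + reads$length[i],
                         reads$strand[i]),
                 reads$seq[i], "+", substr(qual, 1, nchar(reads$seq[i]))),
               con)
  }
  invisible(path)
}
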