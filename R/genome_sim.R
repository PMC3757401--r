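## Synthetic genome generator.
##
## The generator builds, per chromosome: an order-0 background sequence with
## CpG dinucleotides injected explicitly at controlled rates (accidental CpGs
## from the iid draw are removed first, so CpG density is exactly the dialled
## variable); megabase-scale hypomethylated domains which ARE the CpG-poor
## tracts; binary per-CpG methylation states (all-or-none domain character);
## gene models placed preferentially outside the domains; and 50 kb window
## tracks for H3K9Ac (high outside domains) and H3K27Me3 (high inside),
## constructed to be anti-correlated. Gene expression is a monotone
## (exponential-linear) function of the two mark scores plus noise.

MARK_WINDOW <- 50000L        # bp, matches the CpG-density window
PROMOTER_UP <- 1000L         # promoter: 1 kb upstream of TSS ...
PROMOTER_DOWN <- 500L        # ... through 500 bp downstream, strand-aware
EXPR_NOISE_SD <- 0.5         # sd of log-expression noise
GENE_IN_DOMAIN_ACCEPT <- 0.3 # thinning factor making domains gene-poor

#' Simulate a domain-structured methylome genome
#'
#' Generates a `genome_model`: sequences, CpG coordinates with binary
#' methylation states, ground-truth hypomethylated domain intervals, gene
#' models with expression values, and H3K9Ac/H3K27Me3 window tracks. All
#' coordinates are 0-based half-open. Identical configurations (including
#' seed) reproduce identical models.
#'
#' @param config a [sim_config()].
#' @return object of class `genome_model` with elements `sequences` (named
#'   character), `cpg` (per-chromosome list with 0-based `pos` and binary
#'   `meth`), `truth_domains`, `genes`, `marks` and `config`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  chroms <- chrom_names(config$n_chromosomes)
  L <- as.integer(config$genome_length)

  sequences <- setNames(character(length(chroms)), chroms)
  cpg <- setNames(vector("list", length(chroms)), chroms)
  dom_list <- list(); gene_list <- list(); mark_list <- list()

  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    with_seed(child_seed(config$seed, ci * 101), {
      dom <- place_domains(L, config$n_hypo_domains, config$hypo_domain_length)
      seqstr <- intToUtf8(sim_sequence(L, config$gc_content, dom,
                                       config$cpg_rate_high,
                                       config$cpg_rate_low))
      pos <- scan_cpg(seqstr)                       # 0-based C positions
      in_dom <- in_intervals(pos, dom)
      p <- ifelse(in_dom, config$domain_meth, config$background_meth)
      meth <- as.numeric(rbinom(length(pos), 1L, p))

      genes <- place_genes(chrom, L, config$n_genes, dom)
      ## promoter override: active genes (TSS outside domains) carry
      ## hypomethylated promoters; silenced genes (inside) the inverse
      if (nrow(genes) > 0 && length(pos) > 0) {
        tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
        active <- !in_intervals(tss, dom)
        for (gi in seq_len(nrow(genes))) {
          sel <- pos >= genes$promoter_start[gi] & pos < genes$promoter_end[gi]
          if (!any(sel)) next
          pm <- if (active[gi]) config$domain_meth else config$background_meth
          meth[sel] <- as.numeric(rbinom(sum(sel), 1L, pm))
        }
      }

      marks <- sim_marks(chrom, L, dom)
      genes$expression <- sim_expression(genes, marks,
                                         config$expression_coupling)

      sequences[[chrom]] <- seqstr
      cpg[[chrom]] <- list(pos = pos, meth = meth)
      dom_list[[chrom]] <- truth_frame(chrom, L, dom)
      gene_list[[chrom]] <- genes
      mark_list[[chrom]] <- marks
    })
  }

  genes <- do.call(rbind, gene_list)
  rownames(genes) <- NULL
  model <- structure(list(
    sequences = sequences,
    cpg = cpg,
    truth_domains = do.call(rbind, c(dom_list, list(make.row.names = FALSE))),
    genes = genes,
    marks = do.call(rbind, c(mark_list, list(make.row.names = FALSE))),
    config = config), class = "genome_model")
  validate_genome_model(model)
  model
}

## non-overlapping domain placement by rejection sampling
place_domains <- function(L, n, len_range) {
  if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0); ends <- integer(0)
  tries <- 0
  while (length(starts) < n) {
    tries <- tries + 1
    if (tries > 1000 * n)
      stopf("could not place %d non-overlapping hypo domains in %d bp", n, L)
    len <- round(runif(1, len_range[1], len_range[2]))
    if (len >= L) len <- L - 1
    s <- floor(runif(1, 0, L - len))
    if (any(s < ends & s + len > starts)) next
    starts <- c(starts, s); ends <- c(ends, s + len)
  }
  o <- order(starts)
  data.frame(start = as.integer(starts[o]), end = as.integer(ends[o]))
}

## iid background with target GC, accidental CpGs removed, CpGs injected at
## region-specific rates. Replacing the G of an accidental CpG with A/T
## cannot create a new CpG, and injected CpGs are kept >= 2 bp apart.
sim_sequence <- function(L, gc, dom, rate_high, rate_low) {
  codes <- c(65L, 67L, 71L, 84L)  # UTF-8 A, C, G, T
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  b <- codes[sample.int(4L, L, replace = TRUE, prob = p)]
  acc <- which(b == 67L)
  acc <- acc[acc < L]
  acc <- acc[b[acc + 1L] == 71L]
  if (length(acc))
    b[acc + 1L] <- c(65L, 84L)[sample.int(2L, length(acc), replace = TRUE)]

  segs <- segment_by_domains(L, dom)
  for (si in seq_len(nrow(segs))) {
    s <- segs$start[si]; e <- segs$end[si]
    rate <- if (segs$in_domain[si]) rate_low else rate_high
    len <- e - s
    n <- rpois(1, rate * len)
    if (n == 0 || len < 2) next
    cand <- sort(s + sample.int(len - 1L, min(n, len - 1L)) - 1L) # 0-based
    keep <- c(TRUE, diff(cand) >= 2L)
    cand <- cand[keep]
    b[cand + 1L] <- 67L
    b[cand + 2L] <- 71L
  }
  b
}

## partition [0, L) into background / domain segments
segment_by_domains <- function(L, dom) {
  if (nrow(dom) == 0)
    return(data.frame(start = 0L, end = L, in_domain = FALSE))
  cuts <- sort(unique(c(0L, dom$start, dom$end, L)))
  st <- head(cuts, -1); en <- tail(cuts, -1)
  data.frame(start = st, end = en,
             in_domain = in_intervals(st, dom))
}

in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0)
    return(rep(FALSE, length(pos)))
  hit <- IRanges::findOverlaps(
    IRanges::IRanges(pos + 1L, pos + 1L),
    as_iranges0(intervals$start, intervals$end))
  out <- rep(FALSE, length(pos))
  out[S4Vectors::queryHits(hit)] <- TRUE
  out
}

## 0-based positions of the C of every CpG dinucleotide
scan_cpg <- function(seqstr) {
  m <- Biostrings::matchPattern("CG", Biostrings::DNAString(seqstr))
  as.integer(IRanges::start(m)) - 1L
}

truth_frame <- function(chrom, L, dom) {
  if (nrow(dom) == 0)
    return(data.frame(chrom = chrom, start = 0L, end = L,
                      label = "BACKGROUND", stringsAsFactors = FALSE))
  edges <- sort(unique(c(0L, dom$start, dom$end, L)))
  st <- head(edges, -1); en <- tail(edges, -1)
  keep <- en > st
  st <- st[keep]; en <- en[keep]
  data.frame(chrom = chrom, start = st, end = en,
             label = ifelse(in_intervals(st, dom), "HYPO", "BACKGROUND"),
             stringsAsFactors = FALSE)
}

place_genes <- function(chrom, L, n, dom) {
  if (n == 0)
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), expression = numeric(0),
                      promoter_start = integer(0), promoter_end = integer(0),
                      stringsAsFactors = FALSE))
  starts <- integer(0); lens <- integer(0)
  while (length(starts) < n) {
    k <- 2 * (n - length(starts)) + 10
    len <- pmin(pmax(round(rlnorm(k, log(2e4), 0.8)), 2000L), 200000L)
    s <- floor(runif(k, 0, pmax(1, L - len)))
    accept <- ifelse(in_intervals(s, dom),
                     runif(k) < GENE_IN_DOMAIN_ACCEPT, TRUE)
    starts <- c(starts, s[accept]); lens <- c(lens, len[accept])
  }
  starts <- starts[seq_len(n)]; lens <- lens[seq_len(n)]
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(starts + lens[o])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", starts, ends - 1L)
  ps <- ifelse(strand == "+", tss - PROMOTER_UP, tss - PROMOTER_DOWN + 1L)
  pe <- ifelse(strand == "+", tss + PROMOTER_DOWN, tss + PROMOTER_UP + 1L)
  data.frame(id = sprintf("%s_g%04d", chrom, seq_len(n)), chrom = chrom,
             start = starts, end = ends, strand = strand,
             expression = NA_real_,
             promoter_start = pmax(0L, as.integer(ps)),
             promoter_end = pmin(as.integer(L), as.integer(pe)),
             stringsAsFactors = FALSE)
}

## complementary mark landscapes on a fixed window grid: H3K27Me3 tracks the
## hypomethylated domains, H3K9Ac the methylated background.
sim_marks <- function(chrom, L, dom, window = MARK_WINDOW) {
  st <- seq(0L, L - 1L, by = window)
  en <- pmin(st + window, L)
  f <- vapply(seq_along(st), function(i)
    interval_overlap_bp(st[i], en[i], dom$start, dom$end) / (en[i] - st[i]),
    numeric(1))
  k27 <- pmax(0, 0.2 + 0.6 * f + rnorm(length(st), 0, 0.05))
  k9 <- pmax(0, 0.8 - 0.6 * f + rnorm(length(st), 0, 0.05))
  data.frame(chrom = chrom, start = st, end = en,
             h3k9ac = k9, h3k27me3 = k27, stringsAsFactors = FALSE)
}

sim_expression <- function(genes, marks, coupling) {
  if (nrow(genes) == 0) return(numeric(0))
  k9 <- gene_mark_scores(genes, mark_track(marks, "h3k9ac"), "WHOLE")
  k27 <- gene_mark_scores(genes, mark_track(marks, "h3k27me3"), "WHOLE")
  exp(coupling[["h3k9ac"]] * k9 + coupling[["h3k27me3"]] * k27 +
        rnorm(nrow(genes), 0, EXPR_NOISE_SD))
}

#' Extract one histone mark as a window track
#'
#' @param marks the `marks` element of a `genome_model`.
#' @param mark `"h3k9ac"` or `"h3k27me3"`.
#' @return a `window_track` data frame (`chrom`, `start`, `end`, `value`).
#' @export
mark_track <- function(marks, mark = c("h3k9ac", "h3k27me3")) {
  mark <- match.arg(mark)
  structure(data.frame(chrom = marks$chrom, start = marks$start,
                       end = marks$end, value = marks[[mark]],
                       stringsAsFactors = FALSE),
            class = c("window_track", "data.frame"))
}

#' Fully methylate every CpG (SssI methylase control)
#'
#' Returns a copy of the model with `meth_state = 1` at every CpG, the
#' in-silico counterpart of in-vitro SssI treatment: a previously
#' McrBC-resistant hypomethylated genome becomes fully sensitive.
#'
#' @param model a `genome_model`.
#' @return a `genome_model` with all methylation states set to 1.
#' @export
apply_sssi <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  model$cpg <- lapply(model$cpg, function(x) {
    x$meth <- rep(1, length(x$pos)); x
  })
  model
}

validate_genome_model <- function(model) {
  for (chrom in names(model$cpg)) {
    x <- model$cpg[[chrom]]
    if (length(x$pos) != length(x$meth))
      stopf("genome_model: meth/pos length mismatch on %s", chrom)
    if (is.unsorted(x$pos, strictly = TRUE))
      stopf("genome_model: cpg positions not strictly increasing on %s", chrom)
    if (!is_prob(x$meth))
      stopf("genome_model: meth_state outside [0,1] on %s", chrom)
  }
  td <- model$truth_domains
  L <- nchar(model$sequences)
  if (any(td$start < 0) || any(td$end > L[td$chrom]) || any(td$end <= td$start))
    stopf("genome_model: truth domain outside chromosome bounds")
  invisible(model)
}

#' @export
print.genome_model <- function(x, ...) {
  n_cpg <- sum(vapply(x$cpg, function(z) length(z$pos), numeric(1)))
  cat("genome_model:", length(x$sequences), "chromosome(s),",
      format(sum(nchar(x$sequences)), big.mark = ","), "bp,",
      format(n_cpg, big.mark = ","), "CpGs,",
      sum(x$truth_domains$label == "HYPO"), "truth HYPO domain(s),",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}
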