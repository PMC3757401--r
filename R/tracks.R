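## Window tracks, mark/expression correlation and per-gene methylation
## patterns.

new_window_track <- function(chrom, start, end, value, extra = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end, value = value,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, class = c("window_track", "data.frame"))
}

tile_windows <- function(lengths, window) {
  out <- lapply(names(lengths), function(chrom) {
    L <- lengths[[chrom]]
    st <- seq.int(0L, L - 1L, by = window)
    data.frame(chrom = chrom, start = st, end = pmin(st + window, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' CpG density track
#'
#' The per-window CpG density score is `log10(n) + 2`, where `n` is the
#' number of CpG dinucleotides whose C falls inside a fixed-width window
#' (default 50 kb); the +2 offset keeps typical values positive and spreads
#' the low-density range. Windows with zero CpGs score `0` and are flagged.
#'
#' @param model a `genome_model`.
#' @param window window width in bp (default 50000).
#' @return a `window_track` with columns `chrom`, `start`, `end`, `value`,
#'   `n_cpg`, `zero_flag`.
#' @export
cpg_density_track <- function(model, window = 50000L) {
  stopifnot(inherits(model, "genome_model"))
  if (!is_count(window) || window <= 0)
    stopf("cpg_density_track: window must be a positive integer")
  grid <- tile_windows(setNames(nchar(model$sequences),
                                names(model$sequences)), window)
  n <- integer(nrow(grid))
  for (chrom in names(model$cpg)) {
    gi <- which(grid$chrom == chrom)
    pos <- model$cpg[[chrom]]$pos
    idx <- findInterval(pos, grid$start[gi])  # windows are sorted, tiling
    n[gi] <- tabulate(idx, nbins = length(gi))
  }
  value <- ifelse(n > 0, log10(n) + 2, 0)
  new_window_track(grid$chrom, grid$start, grid$end, value,
                   data.frame(n_cpg = n, zero_flag = n == 0))
}

#' Gene density track (gene starts per window)
#'
#' @param genes gene table (`chrom`, `start`, ...).
#' @param lengths named vector of chromosome lengths, or a `genome_model`.
#' @param window window width in bp.
#' @return a `window_track` of raw counts.
#' @export
gene_density_track <- function(genes, lengths, window = 50000L) {
  if (inherits(lengths, "genome_model"))
    lengths <- setNames(nchar(lengths$sequences), names(lengths$sequences))
  grid <- tile_windows(lengths, window)
  n <- integer(nrow(grid))
  for (chrom in names(lengths)) {
    gi <- which(grid$chrom == chrom)
    st <- genes$start[genes$chrom == chrom]
    if (length(st) == 0) next
    idx <- findInterval(st, grid$start[gi])
    n[gi] <- tabulate(idx, nbins = length(gi))
  }
  new_window_track(grid$chrom, grid$start, grid$end, as.numeric(n))
}

#' Pearson correlation between two window tracks
#'
#' @param a,b `window_track`s on the same window grid.
#' @return list (`r`, `p`, `n`, `defined`); `defined` is `FALSE` (with `NA`
#'   statistics) when either track has zero variance.
#' @export
track_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
      !all(a$start == b$start))
    stopf("track_correlation: window grids differ")
  n <- nrow(a)
  if (n < 3) stopf("track_correlation: need at least 3 windows")
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ct <- cor.test(a$value, b$value, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

## region interval for a single gene row, 0-based half-open.
## BODY excludes the 500 bp of gene interior covered by the promoter so the
## promoter/body contrast is clean; WHOLE is the union span of both.
gene_region <- function(gene, region) {
  switch(region,
    PROMOTER = c(gene$promoter_start, gene$promoter_end),
    BODY = {
      if (gene$end - gene$start <= 500L) c(gene$start, gene$end)
      else if (gene$strand == "+") c(gene$start + 500L, gene$end)
      else c(gene$start, gene$end - 500L)
    },
    WHOLE = c(min(gene$start, gene$promoter_start),
              max(gene$end, gene$promoter_end)),
    stopf("unknown region '%s'", region))
}

#' Length-weighted mark score of a gene region
#'
#' Averages a window track over the gene's PROMOTER, BODY or WHOLE region,
#' weighting each overlapping window by its overlap length (equivalent to a
#' per-bp average of the step-function track).
#'
#' @param gene a single gene row (from a `genome_model`'s `genes`).
#' @param mark a `window_track` (see [mark_track()]).
#' @param region `"WHOLE"` (default), `"PROMOTER"` or `"BODY"`.
#' @return numeric score.
#' @export
gene_mark_score <- function(gene, mark, region = "WHOLE") {
  gene_mark_scores(gene, mark, region)
}

#' @rdname gene_mark_score
#' @param genes gene table; returns one score per row.
#' @export
gene_mark_scores <- function(genes, mark, region = "WHOLE") {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    reg <- gene_region(g, region)
    mi <- mark$chrom == g$chrom & mark$start < reg[2] & mark$end > reg[1]
    if (!any(mi)) return(NA_real_)
    w <- pmin(mark$end[mi], reg[2]) - pmax(mark$start[mi], reg[1])
    sum(w * mark$value[mi]) / sum(w)
  }, numeric(1))
}

#' Pearson correlation between gene mark scores and expression
#'
#' The direction of this correlation is the hallmark of the two landscapes:
#' positive for the activating H3K9Ac mark, negative for repressive
#' H3K27Me3.
#'
#' @param genes gene table with an `expression` column.
#' @param mark a `window_track`.
#' @param region region used for the gene score (default WHOLE).
#' @return list (`r`, `p`, `n`, `defined`).
#' @export
mark_expression_correlation <- function(genes, mark, region = "WHOLE") {
  score <- gene_mark_scores(genes, mark, region)
  keep <- is.finite(score) & is.finite(genes$expression)
  n <- sum(keep)
  if (n < 3)
    stopf("mark_expression_correlation: need >= 3 genes with scores")
  if (stats::sd(score[keep]) == 0 || stats::sd(genes$expression[keep]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ct <- cor.test(score[keep], genes$expression[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Promoter/gene-body methylation pattern of genes
#'
#' Computes the mean per-CpG methylation state in the promoter and in the
#' gene body and labels the configuration: promoter hypomethylated with
#' methylated body is the active-gene pattern; the mirror image is the
#' silenced-gene pattern; anything else (or a region without CpGs) is MIXED,
#' with a missing-data flag when either region lacks CpGs.
#'
#' @param model a `genome_model`.
#' @param promoter_cut methylation threshold separating hypo from hyper
#'   (default 0.5), applied to both regions.
#' @return data frame (`id`, `promoter_meth`, `body_meth`, `pattern`,
#'   `missing`).
#' @export
classify_gene_patterns <- function(model, promoter_cut = 0.5) {
  stopifnot(inherits(model, "genome_model"))
  genes <- model$genes
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    x <- model$cpg[[g$chrom]]
    pr <- gene_region(g, "PROMOTER"); bd <- gene_region(g, "BODY")
    pm <- x$meth[x$pos >= pr[1] & x$pos < pr[2]]
    bm <- x$meth[x$pos >= bd[1] & x$pos < bd[2]]
    miss <- length(pm) == 0 || length(bm) == 0
    p <- if (length(pm)) mean(pm) else NA_real_
    b <- if (length(bm)) mean(bm) else NA_real_
    pattern <- if (miss) "MIXED"
      else if (p < promoter_cut && b >= promoter_cut) "ACTIVE_PATTERN"
      else if (p >= promoter_cut && b < promoter_cut) "SILENCED_PATTERN"
      else "MIXED"
    data.frame(id = g$id, promoter_meth = p, body_meth = b,
               pattern = pattern, missing = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname classify_gene_patterns
#' @param gene a single gene row.
#' @param cpg the per-chromosome CpG list (`pos`, `meth`) for the gene's
#'   chromosome.
#' @export
classify_gene_pattern <- function(gene, cpg, promoter_cut = 0.5) {
  fake <- structure(list(sequences = setNames(" ", gene$chrom),
                         cpg = setNames(list(cpg), gene$chrom),
                         genes = gene), class = "genome_model")
  classify_gene_patterns(fake, promoter_cut)
}
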