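## Two-condition comparison: ratio-of-ratios track, smoothing, en-bloc
## domain-change detection and discordantly classified (differential) sites.
## Convention: ratio = control fold change / treated fold change, so values
## above one mean the DNA became hypermethylated after treatment (the
## resistant signal dropped) and vice versa.

#' Ratio-of-ratios differential track
#'
#' @param control,treated `probe_table`s on identical probe grids.
#' @return a `diff_track` data frame (`id`, `chrom`, `start`, `end`,
#'   `ratio_of_ratios`, `smoothed`); `smoothed` is filled by
#'   [smooth_track()].
#' @export
ratio_of_ratios <- function(control, treated) {
  if (nrow(control) != nrow(treated))
    stopf("ratio_of_ratios: probe grids differ in size (%d vs %d)",
          nrow(control), nrow(treated))
  mism <- which(control$id != treated$id | control$chrom != treated$chrom |
                  control$start != treated$start)
  if (length(mism))
    stopf("ratio_of_ratios: probe grids differ, first discordant probe: %s",
          control$id[mism[1]])
  structure(data.frame(
    id = control$id, chrom = control$chrom, start = control$start,
    end = control$end,
    ratio_of_ratios = control$fold_change / treated$fold_change,
    smoothed = NA_real_, stringsAsFactors = FALSE),
    class = c("diff_track", "data.frame"))
}

#' Centered moving-average smoothing of a differential track
#'
#' Windows shrink at chromosome edges (the mean is taken over whatever part
#' of the window exists); `window_probes = 1` is the identity.
#'
#' @param track a `diff_track`.
#' @param window_probes window size in probes (default 25).
#' @return the track with `smoothed` filled.
#' @export
smooth_track <- function(track, window_probes = 25L) {
  if (!is_count(window_probes) || window_probes < 1)
    stopf("smooth_track: window_probes must be a positive integer")
  h_lo <- (window_probes - 1L) %/% 2L
  h_hi <- window_probes %/% 2L
  for (chrom in unique(track$chrom)) {
    ci <- which(track$chrom == chrom)
    x <- track$ratio_of_ratios[ci]
    n <- length(x)
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    lo <- pmax(1L, i - h_lo); hi <- pmin(n, i + h_hi)
    track$smoothed[ci] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  track
}

#' Detect en-bloc methylation changes per domain
#'
#' A domain whose mean smoothed ratio exceeds `1 + delta` gained methylation
#' after treatment; below `1 - delta` it lost methylation; otherwise it is
#' unchanged. The agreement score (fraction of the domain's probes whose own
#' smoothed value supports the verdict) measures blockiness: a coordinated
#' domain-wide shift scores near 1.
#'
#' @param track a smoothed `diff_track` (see [smooth_track()]).
#' @param domains `domain_calls` or truth-domain intervals with a `label`
#'   column.
#' @param delta verdict band half-width (default 0.2).
#' @return data frame (`chrom`, `start`, `end`, `label`, `n_probes`,
#'   `mean_ratio`, `verdict`, `agreement`).
#' @export
detect_enbloc <- function(track, domains, delta = 0.2) {
  if (any(is.na(track$smoothed)))
    stopf("detect_enbloc: track is not smoothed; call smooth_track() first")
  out <- lapply(seq_len(nrow(domains)), function(i) {
    sel <- track$chrom == domains$chrom[i] &
      track$start >= domains$start[i] & track$start < domains$end[i]
    v <- track$smoothed[sel]
    m <- if (length(v)) mean(v) else NA_real_
    verdict <- if (!length(v)) "NO_PROBES"
      else if (m > 1 + delta) "GAINED_METH"
      else if (m < 1 - delta) "LOST_METH"
      else "UNCHANGED"
    agreement <- switch(verdict,
      GAINED_METH = mean(v > 1 + delta),
      LOST_METH = mean(v < 1 - delta),
      UNCHANGED = mean(v >= 1 - delta & v <= 1 + delta),
      NA_real_)
    data.frame(chrom = domains$chrom[i], start = domains$start[i],
               end = domains$end[i],
               label = if ("label" %in% names(domains)) domains$label[i]
                       else NA_character_,
               n_probes = length(v), mean_ratio = m, verdict = verdict,
               agreement = agreement, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Differentially classified probes between two conditions
#'
#' Reports probes called HYPER in condition A but HYPO in condition B, and
#' the converse. Swapping A and B swaps the direction labels exactly.
#'
#' @param calls_a,calls_b outputs of [classify_probes()] for the two
#'   conditions, aligned with `grid`.
#' @param grid the shared `probe_table`.
#' @return data frame (`id`, `chrom`, `start`, `end`, `label_a`, `label_b`,
#'   `direction`).
#' @export
differential_sites <- function(calls_a, calls_b, grid) {
  stopifnot(nrow(calls_a) == nrow(grid), nrow(calls_b) == nrow(grid),
            all(calls_a$id == grid$id), all(calls_b$id == grid$id))
  ab <- calls_a$label == "HYPER" & calls_b$label == "HYPO"
  ba <- calls_a$label == "HYPO" & calls_b$label == "HYPER"
  sel <- ab | ba
  out <- data.frame(
    id = grid$id[sel], chrom = grid$chrom[sel], start = grid$start[sel],
    end = grid$end[sel], label_a = calls_a$label[sel],
    label_b = calls_b$label[sel],
    direction = ifelse(ab[sel], "HYPER_IN_A_HYPO_IN_B",
                       "HYPO_IN_A_HYPER_IN_B"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate differential sites with overlapping genes
#'
#' Any-bp overlap; all overlapping genes are listed (comma-separated), with
#' the longest overlapping gene's length and a >100 kb large-gene flag;
#' intergenic sites are annotated `"none"`.
#'
#' @param sites output of [differential_sites()].
#' @param genes gene table (`id`, `chrom`, `start`, `end`).
#' @param large_gene_bp length above which a gene is flagged large
#'   (default 100 kb).
#' @return `sites` with `genes`, `gene_length`, `large_gene` columns added.
#' @export
annotate_sites <- function(sites, genes, large_gene_bp = 100000L) {
  glen <- genes$end - genes$start
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    ov <- genes$chrom == sites$chrom[i] & genes$start < sites$end[i] &
      genes$end > sites$start[i]
    if (!any(ov))
      return(data.frame(genes = "none", gene_length = NA_integer_,
                        large_gene = FALSE))
    data.frame(genes = paste(genes$id[ov], collapse = ","),
               gene_length = max(glen[ov]),
               large_gene = max(glen[ov]) > large_gene_bp)
  })
  cbind(sites, do.call(rbind, ann))
}
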