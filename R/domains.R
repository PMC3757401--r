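## Fold-change classification and domain segmentation.
##
## Probes with fold change strictly above 2 are called hypomethylated
## (resistant DNA over-represented), strictly below 0.5 hypermethylated;
## boundary values are NEUTRAL. Same-label probe runs, tolerating short
## interleaved NEUTRAL gaps, are merged into domains.

#' Classify probes by fold-change thresholds
#'
#' @param grid a `probe_table` with ratios filled.
#' @param hypo_cut fold change strictly above this is HYPO (default 2).
#' @param hyper_cut fold change strictly below this is HYPER (default 0.5).
#' @return data frame (`id`, `label`) aligned with `grid`; `label` is one of
#'   `"HYPO"`, `"HYPER"`, `"NEUTRAL"`.
#' @export
classify_probes <- function(grid, hypo_cut = 2, hyper_cut = 0.5) {
  stopifnot(inherits(grid, "probe_table"))
  if (!(hyper_cut < hypo_cut))
    stopf("classify_probes: need hyper_cut < hypo_cut")
  bad <- which(!is.finite(grid$fold_change))
  if (length(bad))
    stopf("classify_probes: non-finite fold change at probe %s",
          grid$id[bad[1]])
  label <- rep("NEUTRAL", nrow(grid))
  label[grid$fold_change > hypo_cut] <- "HYPO"
  label[grid$fold_change < hyper_cut] <- "HYPER"
  data.frame(id = grid$id, label = label, stringsAsFactors = FALSE)
}

#' Merge same-label probe runs into methylation domains
#'
#' Consecutive probes of one label (HYPO or HYPER) form a run; up to
#' `max_gap` interleaved NEUTRAL probes are tolerated between them, while a
#' probe of the opposite label always breaks the run. Runs supported by
#' fewer than `min_probes` labelled probes are discarded. NEUTRAL never
#' seeds a domain. The domain interval spans the first to the last labelled
#' probe of the run.
#'
#' @param calls output of [classify_probes()], aligned with `grid`.
#' @param grid the `probe_table` the calls were made on.
#' @param max_gap maximum run of interleaved NEUTRAL probes (default 2).
#' @param min_probes minimum supporting probes per domain (default 5).
#' @return `domain_calls` data frame (`chrom`, `start`, `end`, `label`,
#'   `n_probes`, `mean_fold_change`).
#' @export
segment_domains <- function(calls, grid, max_gap = 2L, min_probes = 5L) {
  stopifnot(nrow(calls) == nrow(grid), all(calls$id == grid$id))
  res <- list()
  for (chrom in unique(grid$chrom)) {
    ci <- which(grid$chrom == chrom)
    lab <- calls$label[ci]
    for (target in c("HYPO", "HYPER")) {
      idx <- which(lab == target)
      if (length(idx) == 0) next
      ## split where the inter-probe gap holds > max_gap probes or any
      ## opposite-label probe
      other <- setdiff(c("HYPO", "HYPER"), target)
      brk <- logical(length(idx) - 1)
      if (length(idx) > 1) {
        for (j in seq_len(length(idx) - 1)) {
          between <- lab[seq(idx[j] + 1L, length.out = idx[j + 1] - idx[j] - 1L)]
          brk[j] <- length(between) > max_gap || any(between == other)
        }
      }
      run_id <- cumsum(c(0L, as.integer(brk)))
      for (r in unique(run_id)) {
        members <- ci[idx[run_id == r]]
        if (length(members) < min_probes) next
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom,
          start = grid$start[members[1]],
          end = grid$end[members[length(members)]],
          label = target, n_probes = length(members),
          mean_fold_change = mean(grid$fold_change[members]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      n_probes = integer(0), mean_fold_change = numeric(0),
                      stringsAsFactors = FALSE)
  else {
    out <- do.call(rbind, res)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("domain_calls", "data.frame")
  out
}

#' Per-chromosome hypo/hyper probe summary
#'
#' Counts hypo- and hypermethylated probes per chromosome and their ratio
#' (the quantity plotted per chromosome to rank, e.g., the most hyper- and
#' hypomethylated chromosomes). With no hypermethylated probes the ratio is
#' reported as `Inf` (or `NaN` when both counts are zero) and flagged.
#'
#' @inheritParams segment_domains
#' @return data frame (`chrom`, `n_hypo_probes`, `n_hyper_probes`,
#'   `hypo_to_hyper_ratio`, `ratio_defined`).
#' @export
summarize_chromosomes <- function(calls, grid) {
  stopifnot(nrow(calls) == nrow(grid), all(calls$id == grid$id))
  out <- lapply(unique(grid$chrom), function(chrom) {
    lab <- calls$label[grid$chrom == chrom]
    nh <- sum(lab == "HYPO"); nr <- sum(lab == "HYPER")
    ratio <- if (nr > 0) nh / nr else if (nh > 0) Inf else NaN
    data.frame(chrom = chrom, n_hypo_probes = nh, n_hyper_probes = nr,
               hypo_to_hyper_ratio = ratio, ratio_defined = nr > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare called domains with simulation ground truth
#'
#' @param domains `domain_calls` (only HYPO calls are compared).
#' @param truth the `truth_domains` element of a `genome_model`.
#' @return list with `jaccard` (base-level Jaccard index between called and
#'   truth HYPO bases) and `boundaries`, a per-truth-domain data frame of
#'   start/end offsets in bp (`NA` when a truth domain attracted no call).
#' @export
compare_to_truth <- function(domains, truth) {
  called <- domains[domains$label == "HYPO", , drop = FALSE]
  th <- truth[truth$label == "HYPO", , drop = FALSE]
  jac <- interval_jaccard(called, th)
  bnd <- lapply(seq_len(nrow(th)), function(i) {
    ov <- called$chrom == th$chrom[i] &
      called$start < th$end[i] & called$end > th$start[i]
    if (!any(ov))
      return(data.frame(chrom = th$chrom[i], truth_start = th$start[i],
                        truth_end = th$end[i],
                        start_offset = NA_real_, end_offset = NA_real_))
    data.frame(chrom = th$chrom[i], truth_start = th$start[i],
               truth_end = th$end[i],
               start_offset = abs(min(called$start[ov]) - th$start[i]),
               end_offset = abs(max(called$end[ov]) - th$end[i]))
  })
  bnd <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(chrom = character(0), truth_start = integer(0),
               truth_end = integer(0), start_offset = numeric(0),
               end_offset = numeric(0))
  rownames(bnd) <- NULL
  list(jaccard = jac, boundaries = bnd)
}

## base-level Jaccard over per-chromosome interval sets
interval_jaccard <- function(a, b) {
  chroms <- union(a$chrom, b$chrom)
  inter <- 0; uni <- 0
  for (chrom in chroms) {
    ia <- a[a$chrom == chrom, , drop = FALSE]
    ib <- b[b$chrom == chrom, , drop = FALSE]
    ra <- IRanges::reduce(as_iranges0(ia$start, ia$end))
    rb <- IRanges::reduce(as_iranges0(ib$start, ib$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ra, rb)))
    uni <- uni + sum(IRanges::width(IRanges::union(ra, rb)))
  }
  if (uni == 0) return(1)  # both empty
  inter / uni
}
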