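## In-silico McrBC digestion.
##
## McrBC recognises two half-sites, each a purine followed by a methylated
## cytosine (Pu-mC), and cleaves between half-site pairs separated by roughly
## 40-3000 bp. Digestion is modelled as deterministic and complete: every
## eligible consecutive half-site pair contributes one cut at the integer
## midpoint between the two half-sites. Hypomethylated DNA carries no
## half-sites and survives as high-molecular-weight fragments, recovered by a
## gel-style length threshold (size_select).

#' Digestion parameters
#'
#' @param min_pair_spacing,max_pair_spacing bp window within which two
#'   consecutive Pu-mC half-sites support cleavage (standard McrBC
#'   enzymology: 40-3000 bp).
#' @param cut_offset_rule only `"MIDPOINT"` is implemented: the cut falls at
#'   the integer midpoint of the half-site pair (reproducible; the enzyme's
#'   distributive ~30 bp offset is irrelevant at kb-scale array resolution).
#' @param size_threshold bp; fragments at least this long count as
#'   "high molecular weight" (near the gel top). The wet protocol gives no
#'   number; 20 kb is the package default.
#' @param meth_call_threshold a CpG counts as methylated for half-site
#'   purposes when its `meth_state` is at least this value.
#' @return object of class `digest_params`.
#' @export
digest_params <- function(min_pair_spacing = 40L, max_pair_spacing = 3000L,
                          cut_offset_rule = "MIDPOINT",
                          size_threshold = 20000L,
                          meth_call_threshold = 0.5) {
  if (!identical(cut_offset_rule, "MIDPOINT"))
    stopf("digest_params: cut_offset_rule must be 'MIDPOINT'")
  if (!is_count(min_pair_spacing) || !is_count(max_pair_spacing) ||
      min_pair_spacing <= 0 || max_pair_spacing <= min_pair_spacing)
    stopf("digest_params: need 0 < min_pair_spacing < max_pair_spacing")
  if (!is_count(size_threshold) || size_threshold <= 0)
    stopf("digest_params: size_threshold must be > 0")
  if (!is_prob(meth_call_threshold))
    stopf("digest_params: meth_call_threshold must be in [0,1]")
  structure(list(min_pair_spacing = as.integer(min_pair_spacing),
                 max_pair_spacing = as.integer(max_pair_spacing),
                 cut_offset_rule = "MIDPOINT",
                 size_threshold = as.integer(size_threshold),
                 meth_call_threshold = meth_call_threshold),
            class = "digest_params")
}

#' Locate McrBC half-sites (Pu-mC) on both strands
#'
#' A plus-strand half-site is a methylated CpG cytosine preceded by A or G; a
#' minus-strand half-site is the complementary cytosine (at CpG position + 1)
#' whose 5' neighbour on the minus strand is a purine, i.e. the base two
#' positions 3' of the CpG on the plus strand is C or T. Positions are
#' 0-based coordinates of the methylated C itself.
#'
#' @param model a `genome_model`.
#' @param params a [digest_params()].
#' @return data frame (`chrom`, `pos`, `strand`, `flank`) sorted by position
#'   within chromosome.
#' @export
find_half_sites <- function(model, params = digest_params()) {
  stopifnot(inherits(model, "genome_model"))
  out <- lapply(names(model$cpg), function(chrom) {
    x <- model$cpg[[chrom]]
    mpos <- x$pos[x$meth >= params$meth_call_threshold]
    if (length(mpos) == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), flank = character(0),
                        stringsAsFactors = FALSE))
    seqstr <- model$sequences[[chrom]]
    L <- nchar(seqstr)
    ## plus strand: base preceding the C (0-based pos-1 -> string index pos)
    has_prev <- mpos >= 1L
    prev <- rep(NA_character_, length(mpos))
    prev[has_prev] <- substring(seqstr, mpos[has_prev], mpos[has_prev])
    plus <- has_prev & prev %in% c("A", "G")
    ## minus strand: C at pos+1; its minus-strand 5' neighbour is the
    ## complement of the plus base at pos+2
    has_next <- mpos + 2L <= L - 1L
    nxt <- rep(NA_character_, length(mpos))
    nxt[has_next] <- substring(seqstr, mpos[has_next] + 3L, mpos[has_next] + 3L)
    minus <- has_next & nxt %in% c("C", "T")
    df <- rbind(
      data.frame(chrom = rep(chrom, sum(plus)), pos = mpos[plus],
                 strand = rep("+", sum(plus)), flank = prev[plus],
                 stringsAsFactors = FALSE),
      data.frame(chrom = rep(chrom, sum(minus)), pos = mpos[minus] + 1L,
                 strand = rep("-", sum(minus)),
                 flank = chartr("CT", "GA", nxt[minus]),
                 stringsAsFactors = FALSE))
    df[order(df$pos), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Digest a genome with in-silico McrBC
#'
#' Introduces a cut at the integer midpoint between every pair of consecutive
#' half-sites whose spacing lies within the eligible window; the resulting
#' fragments tile each chromosome exactly (their lengths always sum to the
#' chromosome length).
#'
#' @inheritParams find_half_sites
#' @return `fragment_set` data frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @export
mcrbc_digest <- function(model, params = digest_params()) {
  hs <- find_half_sites(model, params)
  out <- lapply(names(model$sequences), function(chrom) {
    L <- nchar(model$sequences[[chrom]])
    pos <- hs$pos[hs$chrom == chrom]
    cuts <- integer(0)
    if (length(pos) >= 2) {
      p1 <- pos[-length(pos)]; p2 <- pos[-1]
      d <- p2 - p1
      ok <- d >= params$min_pair_spacing & d <= params$max_pair_spacing
      cuts <- (p1[ok] + p2[ok]) %/% 2L
      cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
    }
    b <- c(0L, cuts, L)
    data.frame(chrom = chrom, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Gel-style size selection of resistant fragments
#'
#' Retains fragments whose length is at least `size_threshold` (the
#' high-molecular-weight material recovered near the gel top), preserving
#' order.
#'
#' @param fragments a `fragment_set` from [mcrbc_digest()].
#' @param size_threshold bp.
#' @return filtered `fragment_set`.
#' @export
size_select <- function(fragments, size_threshold = 20000L) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (!is_count(size_threshold) || size_threshold <= 0)
    stopf("size_select: size_threshold must be a positive integer")
  out <- fragments[(fragments$end - fragments$start) >= size_threshold, ,
                   drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Fragment length histogram (in-silico gel)
#'
#' @param fragments a `fragment_set`.
#' @param breaks passed to [graphics::hist()]-style binning via `cut`;
#'   defaults to log-spaced bins from 10 bp to 10 Mb.
#' @return data frame (`bin_lo`, `bin_hi`, `count`).
#' @export
fragment_length_hist <- function(fragments,
                                 breaks = 10^seq(1, 7, by = 0.25)) {
  len <- fragments$end - fragments$start
  breaks <- sort(unique(c(0, breaks, max(len, breaks))))
  idx <- findInterval(len, breaks, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = cnt)
}
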