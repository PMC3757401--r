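#' @importFrom stats rnorm rbinom rpois runif rlnorm median cor.test setNames
#' @importFrom utils head tail write.table read.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic child seed derivation: one parent stream per run, stage
## offsets keep sub-module draws independent of draw-order changes elsewhere.
## Kept strictly below 2^31 - 1.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset * 16807) %% 2147483587
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

## 0-based half-open intervals -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) &&
  all(x >= 0) && all(x <= 1)

## total overlap (bp) between two 0-based half-open interval sets
interval_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0 || length(b_start) == 0) return(0)
  ia <- IRanges::reduce(as_iranges0(a_start, a_end))
  ib <- IRanges::reduce(as_iranges0(b_start, b_end))
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

chrom_names <- function(n) paste0("chr", seq_len(n))
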