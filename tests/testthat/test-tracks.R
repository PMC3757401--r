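test_that("CpG density is log10(count) + 2 with a zero sentinel", {
  # one window of exactly 1 CpG, one of 100, one empty
  b <- rep("A", 3000)
  b[501:502] <- c("C", "G")
  set.seed(41)
  sites <- seq(1001, 1999, by = 10)[1:100]
  b[sites] <- "C"; b[sites + 1] <- "G"
  m <- toy_model(paste(b, collapse = ""))
  tr <- cpg_density_track(m, window = 1000L)
  expect_equal(tr$value, c(2, 4, 0))
  expect_equal(tr$n_cpg, c(1, 100, 0))
  expect_equal(tr$zero_flag, c(FALSE, FALSE, TRUE))
  expect_error(cpg_density_track(m, window = 0), "window")
})

test_that("CpG density matches a brute-force substring count", {
  set.seed(42)
  for (rep in 1:10) {
    m <- random_seq_model(sample(2000:8000, 1), cpg_n = 150)
    w <- sample(c(250L, 500L, 1000L), 1)
    tr <- cpg_density_track(m, window = w)
    n <- oracle_window_counts(m$sequences[[1]], w)
    expect_equal(tr$n_cpg, as.integer(n))
    expect_equal(tr$value, ifelse(n > 0, log10(n) + 2, 0))
  }
})

test_that("gene density counts gene starts and conserves totals", {
  lengths <- c(chrT = 10000L)
  empty <- data.frame(chrom = character(0), start = integer(0))
  expect_true(all(gene_density_track(empty, lengths, 1000L)$value == 0))
  genes <- data.frame(chrom = "chrT", start = c(100L, 200L, 900L, 5000L))
  tr <- gene_density_track(genes, lengths, 1000L)
  expect_equal(tr$value[1], 3)
  expect_equal(tr$value[6], 1)
  expect_equal(sum(tr$value), nrow(genes))
})

test_that("track correlation matches the textbook formula", {
  mk <- function(v) structure(
    data.frame(chrom = "chrT", start = seq(0, by = 100, length.out = length(v)),
               end = seq(100, by = 100, length.out = length(v)), value = v),
    class = c("window_track", "data.frame"))
  set.seed(43)
  x <- rnorm(50); y <- x + rnorm(50)
  r <- track_correlation(mk(x), mk(y))
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, direct, tolerance = 1e-10)
  expect_equal(track_correlation(mk(x), mk(x))$r, 1)
  expect_equal(track_correlation(mk(x), mk(-x))$r, -1)
  z <- track_correlation(mk(x), mk(rep(1, 50)))
  expect_false(z$defined)
  expect_true(is.na(z$r))
  expect_error(track_correlation(mk(x), mk(y[1:10])), "grids")
})

test_that("per-window fold change anti-correlates with CpG density", {
  # hypo domains sit in CpG-poor sequence and carry high fold changes
  signs <- vapply(51:60, function(seed) {
    m <- small_world(seed)
    rs <- size_select(mcrbc_digest(m))
    g <- make_probe_grid(m, 5000L)
    g <- normalize_probes(simulate_signals(g, rs, 0.2, seed = seed + 1000))
    tr <- cpg_density_track(m)
    win <- findInterval(g$start, tr$start)
    fc_by_win <- tapply(g$fold_change, win, mean)
    idx <- as.integer(names(fc_by_win))
    stats::cor(as.numeric(fc_by_win), tr$value[idx])
  }, numeric(1))
  expect_true(all(signs < 0))
})

test_that("gene mark scores length-weight the overlapping windows", {
  mark <- structure(
    data.frame(chrom = "chrT", start = c(0L, 1000L), end = c(1000L, 2000L),
               value = c(3, 7)),
    class = c("window_track", "data.frame"))
  gene1 <- data.frame(id = "g1", chrom = "chrT", start = 100L, end = 700L,
                      strand = "+", promoter_start = 100L,
                      promoter_end = 600L)
  expect_equal(gene_mark_score(gene1, mark, "BODY"), 3)
  gene2 <- data.frame(id = "g2", chrom = "chrT", start = 500L, end = 1500L,
                      strand = "+", promoter_start = 500L,
                      promoter_end = 1000L)
  expect_equal(gene_mark_score(gene2, mark, "WHOLE"), 5)

  # per-bp oracle on random genes
  set.seed(44)
  for (rep in 1:20) {
    s <- sample(0:1500, 1); e <- s + sample(50:400, 1)
    g <- data.frame(id = "g", chrom = "chrT", start = s, end = e,
                    strand = "+", promoter_start = s, promoter_end = s + 1L)
    per_bp <- vapply(s:(e - 1), function(p)
      mark$value[findInterval(p, mark$start)], numeric(1))
    expect_equal(gene_mark_score(g, mark, "WHOLE"), mean(per_bp))
  }
})

test_that("mark-expression correlation has the expected limits and signs", {
  m <- small_world(45, n_genes = 300)
  k9 <- mark_track(m$marks, "h3k9ac")
  # noise-free monotone-linear expression -> r = 1
  g <- m$genes
  g$expression <- 3 * gene_mark_scores(g, k9, "WHOLE") + 1
  expect_equal(mark_expression_correlation(g, k9)$r, 1)

  # permuted expression: correlation collapses
  set.seed(46)
  rs <- vapply(1:30, function(i) {
    gp <- m$genes
    gp$expression <- sample(gp$expression)
    mark_expression_correlation(gp, k9)$r
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.5)
  expect_lt(abs(mean(rs)), 0.1)

  # the generator's stated coupling: positive for H3K9Ac, negative for
  # H3K27Me3
  r9 <- mark_expression_correlation(m$genes, k9)
  r27 <- mark_expression_correlation(m$genes, mark_track(m$marks, "h3k27me3"))
  expect_gt(r9$r, 0); expect_lt(r9$p, 0.01)
  expect_lt(r27$r, 0); expect_lt(r27$p, 0.01)
})

test_that("gene methylation patterns classify promoter/body contrast", {
  # construct CpGs directly: promoter [0,1500), body [1500,10000)
  gene <- data.frame(id = "g1", chrom = "chrT", start = 1000L, end = 10000L,
                     strand = "+", promoter_start = 0L, promoter_end = 1500L)
  cpgs <- function(pm, bm) list(
    pos = c(seq(10L, 1400L, by = 100L), seq(2000L, 9000L, by = 100L)),
    meth = c(rep(pm, 14), rep(bm, 71)))
  p <- classify_gene_pattern(gene, cpgs(0.05, 0.9))
  expect_equal(p$pattern, "ACTIVE_PATTERN")
  expect_equal(p$promoter_meth, 0.05)
  expect_equal(p$body_meth, 0.9)
  expect_equal(classify_gene_pattern(gene, cpgs(0.9, 0.05))$pattern,
               "SILENCED_PATTERN")
  expect_equal(classify_gene_pattern(gene, cpgs(0.9, 0.9))$pattern, "MIXED")
  # no CpGs at all: missing flag, no exception
  none <- classify_gene_pattern(gene, list(pos = integer(0),
                                           meth = numeric(0)))
  expect_true(none$missing)
  expect_equal(none$pattern, "MIXED")
})

test_that("active-pattern genes out-express silenced-pattern genes", {
  m <- small_world(47, n_genes = 250)
  pat <- classify_gene_patterns(m)
  expr <- m$genes$expression
  act <- expr[pat$pattern == "ACTIVE_PATTERN"]
  sil <- expr[pat$pattern == "SILENCED_PATTERN"]
  expect_gt(length(act), 20)
  expect_gt(length(sil), 5)
  expect_gt(mean(act), mean(sil))
})
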