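test_that("conversion retains methylated CpG cytosines only", {
  s <- "ACGTCCACGA"      # CpGs at 0-based 1 and 7; other Cs at 4, 5
  full <- bisulfite_convert(s, c(1L, 7L), c(1, 1), seed = 1)
  expect_equal(full, "ACGTTTACGA")
  none <- bisulfite_convert(s, c(1L, 7L), c(0, 0), seed = 1)
  expect_equal(none, "ATGTTTATGA")
  expect_false(grepl("C", none))
  # partial conversion efficiency spares some non-CpG Cs
  set.seed(2)
  some <- replicate(200, bisulfite_convert("ACCCCCCCCA", integer(0),
                                           numeric(0), efficiency = 0.5))
  frac_c <- mean(unlist(strsplit(some, "")) == "C")
  expect_gt(frac_c, 0.3); expect_lt(frac_c, 0.6)
})

test_that("half-methylated CpGs retain ~50% of cytosines across molecules", {
  set.seed(3)
  reps <- replicate(400, substr(bisulfite_convert("ACGA", 1L, 0.5), 2, 2))
  p <- mean(reps == "C")
  expect_gt(p, 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(p, 0.5 + 3 * sqrt(0.25 / 400))
})

test_that("read simulation hits target coverage and is seed-deterministic", {
  m <- small_world(61, genome_length = 2e5, n_hypo_domains = 1,
                   hypo_domain_length = c(3e4, 5e4), n_genes = 10)
  expect_equal(nrow(simulate_bisreads(m, "chr1", 0, 10000, coverage = 0)), 0)
  r <- simulate_bisreads(m, "chr1", 0, 10000, coverage = 30, seed = 4)
  expect_equal(nrow(r), 3000)
  expect_true(all(r$start >= 0 & r$start + r$length <= 10000))
  r2 <- simulate_bisreads(m, "chr1", 0, 10000, coverage = 30, seed = 4)
  expect_identical(r, r2)
  expect_error(simulate_bisreads(m, "chr1", 0, 50, coverage = 1),
               "read length")
})

test_that("methylation calling tallies C/T evidence per strand correctly", {
  # hand-built reads over one CpG at 0-based 10 on a 30 bp refernce:
  # 3 methylated plus reads (C at offset 10), 7 unmethylated mixed-strand
  plus_m <- paste0(strrep("T", 10), "CG", strrep("T", 18))
  plus_u <- paste0(strrep("T", 10), "TG", strrep("T", 18))
  # minus-strand read stored 5'->3' on the minus strand: the complementary
  # C of the CpG sits at read index (end-1) - (pos+1) = 29 - 11 = 18
  minus_u <- paste0(strrep("A", 18), "T", strrep("A", 11))
  reads <- data.frame(
    chrom = "chrT", start = 0L, length = 30L,
    strand = c(rep("+", 6), rep("-", 4)),
    seq = c(rep(plus_m, 3), rep(plus_u, 3), rep(minus_u, 4)),
    stringsAsFactors = FALSE)
  calls <- call_methylation(reads, 10L, min_coverage = 5)
  expect_equal(calls$n_C, 3)
  expect_equal(calls$n_T, 7)
  expect_equal(calls$meth_fraction, 0.3)
  expect_equal(calls$coverage, 10)
  expect_false(calls$low_coverage)
  # all-methylated site
  calls2 <- call_methylation(reads[1:3, ], 10L)
  expect_equal(calls2$meth_fraction, 1)
  expect_true(calls2$low_coverage)
})

test_that("plus and minus reads report a shared CpG consistently", {
  # fully methylated model: every overlapping read must report C
  b <- rep("T", 400); b[201:202] <- c("C", "G")
  m <- toy_model(paste(b, collapse = ""), meth = 1)
  r <- simulate_bisreads(m, "chrT", 0, 400, coverage = 40, seed = 5)
  calls <- call_methylation(r, m$cpg[[1]]$pos)
  expect_equal(calls$meth_fraction, 1)
  expect_gt(calls$coverage, 10)
  # coverage never exceeds the number of overlapping reads
  n_overlap <- sum(r$start <= 201 & r$start + r$length > 200)
  expect_lte(calls$coverage, n_overlap)
})

test_that("meth_fraction recovers an intermediate truth within binomial error", {
  # truth p = 0.85 at every CpG, 30x coverage: MAE < 2*sqrt(p(1-p)/30)
  b <- rep("T", 10000)
  sites <- seq(100L, 9800L, by = 200L)
  b[sites + 1] <- "C"; b[sites + 2] <- "G"
  m <- toy_model(paste(b, collapse = ""), meth = 0.85)
  r <- simulate_bisreads(m, "chrT", 0, 10000, coverage = 30, seed = 6)
  calls <- call_methylation(r, m$cpg[[1]]$pos)
  mae <- mean(abs(calls$meth_fraction - 0.85))
  expect_lt(mae, 2 * sqrt(0.85 * 0.15 / 30))
})

test_that("domain concordance separates hypo from background sites", {
  dom <- data.frame(chrom = "chrT", start = 0L, end = 5000L, label = "HYPO",
                    stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chrT",
                      pos = c(100L, 200L, 300L, 6000L, 7000L),
                      n_C = c(0L, 0L, 1L, 10L, 9L),
                      n_T = c(10L, 10L, 9L, 0L, 1L),
                      coverage = 10L,
                      meth_fraction = c(0, 0, 0.1, 1, 0.9),
                      low_coverage = FALSE, stringsAsFactors = FALSE)
  v <- bis_validate_domains(calls, dom)
  expect_equal(v$concordance, 1)
  expect_lt(v$mean_meth_hypo, 0.1)
  expect_gt(v$mean_meth_outside, 0.9)
  # random labels give chance-level concordance
  set.seed(7)
  rand <- data.frame(chrom = "chrT", pos = sample(0:9999, 400),
                     n_C = 0L, n_T = 10L, coverage = 10L,
                     meth_fraction = sample(c(0, 1), 400, replace = TRUE),
                     low_coverage = FALSE, stringsAsFactors = FALSE)
  vr <- bis_validate_domains(rand, dom)
  expect_gt(vr$concordance, 0.35); expect_lt(vr$concordance, 0.65)
})

test_that("reads round-trip to FASTQ", {
  m <- toy_model(paste(rep(c("A", "C", "G", "T"), 50), collapse = ""))
  r <- simulate_bisreads(m, "chrT", 0, 200, coverage = 5, read_len = 50L,
                         seed = 8)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(r, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * nrow(r))
  expect_equal(lines[seq(2, length(lines), by = 4)], r$seq)
})
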