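test_that("ratio-of-ratios follows the sign convention and checks grids", {
  ctrl <- fc_grid(c(2, 1, 0.5, 4))
  expect_equal(ratio_of_ratios(ctrl, ctrl)$ratio_of_ratios, rep(1, 4))
  halved <- ctrl
  halved$fold_change <- ctrl$fold_change / 2
  # treated fold change halved -> DNA hypermethylated after treatment
  expect_equal(ratio_of_ratios(ctrl, halved)$ratio_of_ratios, rep(2, 4))
  other <- fc_grid(c(2, 1, 0.5, 4), chrom = "chrU")
  expect_error(ratio_of_ratios(ctrl, other), ctrl$id[1], fixed = TRUE)
  expect_error(ratio_of_ratios(ctrl, ctrl[1:2, ]), "size")
})

test_that("swapping conditions inverts the track exactly", {
  set.seed(71)
  a <- fc_grid(exp(rnorm(100)))
  b <- fc_grid(exp(rnorm(100)))
  expect_equal(ratio_of_ratios(a, b)$ratio_of_ratios,
               1 / ratio_of_ratios(b, a)$ratio_of_ratios)
})

test_that("smoothing is a shrinking-window centered moving average", {
  tr <- ratio_of_ratios(fc_grid(rep(3, 20)), fc_grid(rep(1, 20)))
  s <- smooth_track(tr, 5)
  expect_equal(s$smoothed, rep(3, 20))
  # window 1 is the identity
  set.seed(72)
  tr2 <- ratio_of_ratios(fc_grid(exp(rnorm(50))), fc_grid(exp(rnorm(50))))
  expect_equal(smooth_track(tr2, 1)$smoothed, tr2$ratio_of_ratios)
  # brute-force windowed mean, shrinking at the edges
  w <- 7; h <- 3
  s2 <- smooth_track(tr2, w)
  brute <- vapply(seq_len(50), function(i)
    mean(tr2$ratio_of_ratios[max(1, i - h):min(50, i + h)]), numeric(1))
  expect_equal(s2$smoothed, brute)
  expect_error(smooth_track(tr2, 0), "window_probes")
})

test_that("en-bloc verdicts and agreement behave on constructed domains", {
  n <- 30
  vals <- c(rep(2, 10), rep(1, 10), rep(0.5, 10))
  tr <- ratio_of_ratios(fc_grid(vals, spacing = 100L), fc_grid(rep(1, n)))
  tr <- smooth_track(tr, 1)
  doms <- data.frame(chrom = "chrT",
                     start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L),
                     label = "HYPO", stringsAsFactors = FALSE)
  rep_ <- detect_enbloc(tr, doms, delta = 0.2)
  expect_equal(rep_$verdict, c("GAINED_METH", "UNCHANGED", "LOST_METH"))
  expect_equal(rep_$agreement, c(1, 1, 1))
  expect_equal(rep_$mean_ratio, c(2, 1, 0.5))
  expect_error(detect_enbloc(ratio_of_ratios(fc_grid(1:3), fc_grid(1:3)),
                             doms), "smooth")
})

test_that("differential sites are discordant label pairs with direction", {
  g <- fc_grid(rep(1, 6))
  a <- data.frame(id = g$id,
                  label = c("HYPER", "HYPO", "NEUTRAL", "HYPER", "HYPO",
                            "NEUTRAL"), stringsAsFactors = FALSE)
  b <- data.frame(id = g$id,
                  label = c("HYPO", "HYPER", "HYPO", "HYPER", "HYPO",
                            "NEUTRAL"), stringsAsFactors = FALSE)
  s <- differential_sites(a, b, g)
  expect_equal(s$id, g$id[1:2])
  expect_equal(s$direction, c("HYPER_IN_A_HYPO_IN_B", "HYPO_IN_A_HYPER_IN_B"))
  # identical call sets -> empty
  expect_equal(nrow(differential_sites(a, a, g)), 0)
  # swap is a mirror image
  s_rev <- differential_sites(b, a, g)
  expect_equal(s_rev$id, s$id)
  expect_equal(s_rev$direction,
               c("HYPO_IN_A_HYPER_IN_B", "HYPER_IN_A_HYPO_IN_B"))
})

test_that("differential site counts match a brute-force comparison", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 200
    g <- fc_grid(rep(1, n))
    labs <- c("HYPO", "HYPER", "NEUTRAL")
    a <- data.frame(id = g$id, label = sample(labs, n, replace = TRUE),
                    stringsAsFactors = FALSE)
    b <- data.frame(id = g$id, label = sample(labs, n, replace = TRUE),
                    stringsAsFactors = FALSE)
    s <- differential_sites(a, b, g)
    brute <- 0
    for (i in seq_len(n))
      if ((a$label[i] == "HYPER" && b$label[i] == "HYPO") ||
          (a$label[i] == "HYPO" && b$label[i] == "HYPER"))
        brute <- brute + 1
    expect_equal(nrow(s), brute)
  }
})

test_that("site annotation lists overlapping genes and flags large ones", {
  genes <- data.frame(id = c("big", "small"), chrom = "chrT",
                      start = c(1000L, 200000L), end = c(151000L, 220000L),
                      stringsAsFactors = FALSE)
  sites <- data.frame(id = c("s1", "s2", "s3"), chrom = "chrT",
                      start = c(50000L, 500000L, 210000L),
                      end = c(50060L, 500060L, 210060L),
                      label_a = "HYPER", label_b = "HYPO",
                      direction = "HYPER_IN_A_HYPO_IN_B",
                      stringsAsFactors = FALSE)
  ann <- annotate_sites(sites, genes)
  expect_equal(ann$genes, c("big", "none", "small"))
  expect_equal(ann$large_gene, c(TRUE, FALSE, FALSE))
  expect_equal(ann$gene_length[1], 150000L)
  # brute-force interval intersection on random instances
  set.seed(74)
  for (rep in 1:10) {
    gs <- sort(sample(0:100000, 10))
    genes2 <- data.frame(id = paste0("g", 1:10), chrom = "chrT",
                         start = gs, end = gs + sample(1000:50000, 10),
                         stringsAsFactors = FALSE)
    ss <- sort(sample(0:150000, 20))
    sites2 <- data.frame(id = paste0("s", 1:20), chrom = "chrT",
                         start = ss, end = ss + 60L, label_a = "HYPER",
                         label_b = "HYPO", direction = "HYPER_IN_A_HYPO_IN_B",
                         stringsAsFactors = FALSE)
    ann2 <- annotate_sites(sites2, genes2)
    for (i in 1:20) {
      hits <- genes2$id[genes2$start < sites2$end[i] &
                          genes2$end > sites2$start[i]]
      expected <- if (length(hits)) paste(hits, collapse = ",") else "none"
      expect_equal(ann2$genes[i], expected)
    }
  }
})
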