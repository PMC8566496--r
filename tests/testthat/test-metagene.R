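# Scaled metagenes, anchored profiles, promoter-density series and the
# rank-based comparison.

test_that("scaled metagene of constant coverage is flat and scales linearly", {
  tr <- manual_track(rep(4, 40000))
  genes <- gene_panel(data.frame(id = c("a", "b"), chrom = "chrT",
                                 strand = c("+", "-"),
                                 start = c(5000, 20000),
                                 end = c(12000, 31000)))
  p <- scaled_metagene(tr, genes, body_bins = 20, flank = 1000,
                       flank_bin = 50)
  expect_equal(length(p$values), 20 + 2 * 20)
  expect_equal(p$values, rep(4, length(p$values)))
  expect_equal(p$n_genes, 2L)

  p2 <- scaled_metagene(manual_track(rep(4, 40000) * 2.5), genes,
                        body_bins = 20, flank = 1000, flank_bin = 50)
  expect_equal(p2$values, p$values * 2.5)
})

test_that("scaled metagene equals brute-force sub-interval means", {
  set.seed(14)
  v <- runif(30000)
  tr <- manual_track(v)
  g <- one_gene(10000, 17000, "+")
  nb <- 10L
  fl <- 500L
  p <- scaled_metagene(tr, g, body_bins = nb, flank = fl, flank_bin = 50)
  # oracle: direct per-sub-interval means over the 0-based windows
  body <- v[10001:17000]
  L <- length(body)
  bounds <- floor(seq_len(nb) * L / nb)
  oracle_body <- vapply(seq_len(nb), function(i) {
    lo <- if (i == 1) 0 else bounds[i - 1]
    mean(body[(lo + 1):bounds[i]])
  }, numeric(1))
  oracle_up <- vapply(seq_len(fl / 50), function(i)
    mean(v[(10000 - fl + (i - 1) * 50 + 1):(10000 - fl + i * 50)]),
    numeric(1))
  expect_equal(p$values[(fl / 50 + 1):(fl / 50 + nb)], oracle_body)
  expect_equal(p$values[seq_len(fl / 50)], oracle_up)
})

test_that("a minus-strand gene with mirrored coverage gives the same profile", {
  set.seed(15)
  G <- 30000
  v <- runif(G)
  gp <- one_gene(8000, 15000, "+")
  gm <- one_gene(G - 15000, G - 8000, "-")
  pp <- scaled_metagene(manual_track(v), gp, body_bins = 25,
                        flank = 1000, flank_bin = 100)
  pm <- scaled_metagene(manual_track(rev(v)), gm, body_bins = 25,
                        flank = 1000, flank_bin = 100)
  expect_equal(pm$values, pp$values)
})

test_that("anchored profiles average fixed windows in transcription orientation", {
  G <- 30000
  tr <- manual_track(rep(2, G))
  genes <- gene_panel(data.frame(id = c("a", "b"), chrom = "chrT",
                                 strand = c("+", "-"),
                                 start = c(5000, 18000),
                                 end = c(9000, 26000)))
  p <- anchor_profile(tr, genes, anchor = "TSS", window = 1000, bin = 50)
  expect_equal(p$values, rep(2, 40))
  expect_equal(p$position[1], -1000)

  # point mass at each TSS yields a single central peak
  v <- numeric(G)
  v[5001] <- 100    # TSS of 'a' (0-based 5000)
  v[26000] <- 100   # TSS of 'b' (0-based 25999, minus strand)
  pk <- anchor_profile(manual_track(v), genes, anchor = "TSS",
                       window = 500, bin = 50)
  expect_equal(sum(pk$values > 0), 1L)
  expect_equal(which(pk$values > 0), 11L)  # first downstream bin [0, 50)

  # 3-gene oracle vs a brute-force average at the TTS
  set.seed(16)
  v2 <- runif(G)
  genes3 <- gene_panel(data.frame(
    id = c("a", "b", "c"), chrom = "chrT", strand = c("+", "-", "+"),
    start = c(5000, 18000, 9000), end = c(9000, 26000, 14000)))
  pr <- anchor_profile(manual_track(v2), genes3, anchor = "TTS",
                       window = 600, bin = 30)
  oracle <- rowMeans(vapply(seq_len(3), function(i) {
    a <- genes3$tts[i]
    w <- if (genes3$strand[i] == "+") v2[(a - 600 + 1):(a + 600)]
         else rev(v2[(a - 600 + 1):(a + 600)])
    colMeans(matrix(w, nrow = 30))
  }, numeric(40)))
  expect_equal(pr$values, oracle)
})

test_that("promoter series track per-gene 5'-bin densities over time", {
  set.seed(17)
  v <- runif(40000) + 0.2
  genes <- gene_panel(data.frame(
    id = c("a", "b", "c"), chrom = "chrT", strand = c("+", "-", "+"),
    start = c(3000, 12000, 25000), end = c(9000, 20000, 33000)))
  t1 <- manual_track(v)
  t2 <- manual_track(v * 2)
  s <- promoter_series(list(t1, t1), genes, times = c(0, 10))
  expect_equal(s$densities[, 1], s$densities[, 2])
  s2 <- promoter_series(list(t1, t2), genes, times = c(0, 10))
  expect_equal(s2$medians[[2]], 2 * s2$medians[[1]])
  expect_error(promoter_series(list(t1), genes, times = 0), "at least 2")
})

test_that("percent decrease follows 100 * (1 - central(t1)/central(t0))", {
  fake_series <- function(m0, m1) {
    structure(list(times = c(0, 20),
                   medians = c(t0 = m0, t20 = m1),
                   means = c(m0, m1),
                   densities = matrix(c(m0, m1), 1),
                   gene_ids = "g"),
              class = "PromoterSeries")
  }
  expect_equal(percent_decrease(fake_series(100, 52.3), 0, 20), 47.7)
  expect_equal(percent_decrease(fake_series(5, 5), 0, 20), 0)
  expect_equal(percent_decrease(fake_series(10, 12), 0, 20), -20)
  expect_error(percent_decrease(fake_series(0, 1), 0, 20), "zero")
  expect_error(percent_decrease(fake_series(1, 1), 0, 30), "not in series")
})

test_that("the rank comparison matches the textbook tie-corrected statistic", {
  fake <- function(x, tt = 20) {
    structure(list(times = tt, densities = matrix(x, ncol = 1),
                   medians = stats::median(x), means = mean(x),
                   gene_ids = as.character(seq_along(x))),
              class = "PromoterSeries")
  }
  x <- c(1.2, 3.4, 3.4, 0.5, 9.1, 2.2)
  y <- c(2.2, 7.7, 0.1, 5.5, 5.5, 8.8, 1.1)
  out <- compare_distributions(fake(x), fake(y), 20)
  expect_equal(out$statistic, kw_statistic(x, y))
  expect_equal(out$df, 1)

  # same distribution in both groups: statistic near 0, p near 1
  z <- seq_len(10)
  same <- compare_distributions(fake(z), fake(z), 20)
  expect_lt(same$statistic, 0.01)
  expect_gt(same$p_value, 0.9)

  # disjoint ranges at n = 100: overwhelming evidence
  set.seed(18)
  lo <- runif(100, 0, 1)
  hi <- runif(100, 10, 11)
  sep <- compare_distributions(fake(lo), fake(hi), 20)
  expect_lt(sep$p_value, 0.001)

  expect_error(compare_distributions(fake(c(1, 2)), fake(z), 20),
               "fewer than 3")
})
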