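# Kinetic simulator: closed-form limits, visibility model, read
# sampling and dataset generation.

sim_genes2 <- function(lens = c(10000, 20000)) {
  gene_panel(data.frame(id = paste0("g", seq_along(lens)), chrom = "chrS",
                        strand = rep_len(c("+", "-"), length(lens)),
                        start = seq(5000, by = 50000,
                                    length.out = length(lens)),
                        end = seq(5000, by = 50000,
                                  length.out = length(lens)) + lens))
}

empty_state <- function(genes) {
  list(U = integer(nrow(genes)), R = integer(nrow(genes)),
       E_gene = integer(0), E_pos = numeric(0),
       T_gene = integer(0), T_left = numeric(0),
       gene_length = genes$length)
}

test_that("an elongating molecule advances deterministically when jitter is off", {
  genes <- sim_genes2()
  cfg <- sim_config(n_genes = 2, k_init = 0, k_release = 0, v = 2000,
                    v_sd = 0, rho = 0, seed = 1)
  st <- empty_state(genes)
  st$E_gene <- 1L
  st$E_pos <- 500
  st2 <- sim_step(st, cfg, in_block = FALSE)
  expect_equal(st2$E_pos, 500 + 2000 * cfg$dt)
  for (k in 1:20) st2 <- sim_step(st2, cfg, in_block = FALSE)
  expect_equal(st2$E_pos, 500 + 21 * 2000 * cfg$dt)
})

test_that("molecules are conserved without initiation when recycling is total", {
  set.seed(2)
  genes <- sim_genes2(c(3000, 4000))
  cfg <- sim_config(n_genes = 2, k_init = 0, k_release = 2, v = 2000,
                    v_sd = 100, term_dwell = 0.5, rho = 1, seed = 1)
  st <- empty_state(genes)
  st$U <- c(5L, 3L)
  st$R <- c(2L, 4L)
  total0 <- sum(st$U) + sum(st$R)
  for (k in 1:400) st <- sim_step(st, cfg, in_block = FALSE)
  total <- sum(st$U) + sum(st$R) + length(st$E_pos) + length(st$T_gene)
  expect_equal(total, total0)   # cycles through E and T included

  # infinite dwell also conserves (molecules pile up terminating)
  cfg2 <- sim_config(n_genes = 2, k_init = 0, k_release = 2,
                     term_dwell = Inf, rho = 0, seed = 1)
  st <- empty_state(genes)
  st$U <- c(5L, 3L)
  for (k in 1:400) st <- sim_step(st, cfg2, in_block = FALSE)
  total <- sum(st$U) + sum(st$R) + length(st$E_pos) + length(st$T_gene)
  expect_equal(total, 8)
})

test_that("unreleased molecules are invisible and blocked from release", {
  genes <- sim_genes2()
  cfg <- sim_config(n_genes = 2, k_init = 0.5, k_release = 2, seed = 1)
  st <- empty_state(genes)
  st$U <- c(10L, 7L)
  set.seed(3)
  for (k in 1:200) st <- sim_step(st, cfg, in_block = TRUE)
  occ <- visible_occupancy(st)
  expect_equal(sum(unlist(occ)), 0)          # U never shows up
  expect_equal(length(st$E_pos), 0L)         # and never releases in block
  expect_gt(sum(st$U), 17)                   # initiation continues
})

test_that("per-step probabilities above the tau-leap bound are refused", {
  expect_error(sim_config(k_release = 2, dt = 0.2), "smaller dt")
  cfg <- sim_config(k_release = 2, dt = 0.05)
  st <- empty_state(sim_genes2())
  expect_error(sim_step(st, cfg, in_block = FALSE, dt = 0.5), "smaller dt")
})

test_that("visible occupancy bins molecules in transcription coordinates", {
  genes <- sim_genes2(c(10000, 20000))
  st <- empty_state(genes)
  st$E_gene <- c(1L, 2L)
  st$E_pos <- c(1500, 50)
  st$R <- c(2L, 0L)
  st$T_gene <- 2L
  st$T_left <- 1
  occ <- visible_occupancy(st, bin_width = 100)
  expect_equal(occ[[1]][16], 1)       # position 1500 in the [1500,1600) bin
  expect_equal(occ[[1]][1], 2)        # recycled molecules sit at the TSS
  expect_equal(occ[[2]][1], 1)        # elongating at +50
  expect_equal(occ[[2]][200], 1)      # terminating molecule at the TTS
  expect_equal(sum(unlist(occ)), 5)   # total = number of visible molecules
  expect_length(occ[[1]], 100)
})

test_that("the retreating 5' edge during a block moves at the velocity", {
  # steady uniform body occupancy, then block: the trailing edge of the
  # elongating cohort is at v * t (no release feeds the 5' end)
  genes <- sim_genes2(100000)
  cfg <- sim_config(n_genes = 1, k_init = 0, k_release = 0, v = 2000,
                    v_sd = 0, rho = 0, seed = 1)
  st <- empty_state(genes)
  st$E_gene <- rep(1L, 200)
  st$E_pos <- seq(0, 99000, length.out = 200)
  for (t_min in c(10, 20)) {
    steps <- t_min / cfg$dt - (if (t_min == 10) 0 else 10 / cfg$dt)
    for (k in seq_len(steps)) st <- sim_step(st, cfg, in_block = TRUE)
    expect_equal(min(st$E_pos), 2000 * t_min,
                 tolerance = 1e-8)
  }
})

test_that("read sampling respects occupancy weights, depth and strand", {
  genes <- sim_genes2(c(10000, 20000))
  genome <- c(chrS = 100000L)
  occ <- list(integer(200), integer(400))
  occ[[1]][61] <- 50        # all gene-1 mass in tx bin [3000, 3050)
  attr(occ, "bin_width") <- 50L
  reads <- sample_reads(occ, genes, genome, depth = 500,
                        read_length = 36, background = 0)
  expect_length(reads, 500L)
  expect_true(all(as.character(GenomicRanges::seqnames(reads)) == "chrS"))
  expect_true(all(as.character(GenomicRanges::strand(reads)) == "+"))
  p5 <- GenomicRanges::start(reads) - 1L   # plus-strand 5' end, 0-based
  tx <- p5 - genes$start[1]
  expect_true(all(tx >= 3000 & tx < 3050))

  # zero occupancy with zero background cannot be sampled
  occ0 <- list(integer(200), integer(400))
  attr(occ0, "bin_width") <- 50L
  expect_error(sample_reads(occ0, genes, genome, depth = 10,
                            background = 0), "nothing to sample")
  # ... but pure background fills the request
  bg <- sample_reads(occ0, genes, genome, depth = 100, background = 0.05)
  expect_length(bg, 100L)
})

test_that("multinomial sampling reproduces a uniform occupancy profile", {
  set.seed(4)
  genes <- sim_genes2(10000)
  genome <- c(chrS = 100000L)
  occ <- list(rep(10L, 200))
  attr(occ, "bin_width") <- 50L
  reads <- sample_reads(occ, genes, genome, depth = 1e5, background = 0)
  p5 <- GenomicRanges::start(reads) - 1L
  tx <- p5 - genes$start[1]
  counts <- tabulate(tx %/% 50 + 1, 200)
  gof <- stats::chisq.test(counts, p = rep(1 / 200, 200))
  expect_gt(gof$p.value, 0.01)
})

test_that("timecourse generation writes a complete, deterministic dataset", {
  sched <- drug_schedule(block_samples = c(0, 10),
                         washout_samples = c(0, 10), burn_in = 5)
  cfgs <- list(control = sim_config(n_genes = 5,
                                    gene_length = c(5000, 20000),
                                    depth = 5000, seed = 11),
               depleted = sim_config(n_genes = 5,
                                     gene_length = c(5000, 20000),
                                     rho = 0.2, v = 1200, depth = 5000,
                                     seed = 12))
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  out <- make_timecourse(cfgs, sched, d1)
  beds <- list.files(d1, pattern = "\\.bed$")
  expect_length(beds, 2 * 4)     # 2 conditions x (2 block + 2 washout)
  expect_true(all(c("genes.tsv", "chrom.sizes", "truth.json",
                    "manifest.json") %in% list.files(d1)))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$conditions$depleted$config$rho, 0.2)

  make_timecourse(cfgs, sched, d2)
  md5 <- function(d) unname(tools::md5sum(
    file.path(d, list.files(d, pattern = "\\.bed$"))))
  expect_identical(md5(d1), md5(d2))

  # both conditions share the gene panel written once
  g <- load_genes(file.path(d1, "genes.tsv"),
                  read_chrom_sizes(file.path(d1, "chrom.sizes")))
  expect_equal(nrow(g), 5L)
})
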