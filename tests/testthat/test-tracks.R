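# Coverage-track layer: BED parsing, 5'-anchored extension,
# depth-normalised coverage and track I/O.

test_that("read_bed maps BED6 fields and preserves order", {
  path <- bed_file(c("chr1", "chr2"), c(100, 0), c(136, 50), c("+", "-"))
  gr <- read_bed(path)
  expect_equal(length(gr), 2L)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr) - 1L, c(100L, 0L))  # back to 0-based
  expect_equal(GenomicRanges::end(gr), c(136L, 50L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
})

test_that("read_bed handles empty files and round-trips write_bed", {
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(read_bed(empty), 0L)

  path <- bed_file("chr1", c(5, 200), c(41, 236), c("-", "+"))
  gr <- read_bed(path)
  out <- tempfile(fileext = ".bed")
  write_bed(gr, out)
  expect_identical(unname(as.character(read.table(out, sep = "\t")[[2]])),
                   c("5", "200"))
  expect_equal(read_bed(out), gr)
})

test_that("read_bed rejects malformed lines, naming the line number", {
  path <- bed_file("chr1", c(0, 200, 10), c(36, 100, 46), c("+", "+", "+"))
  expect_error(read_bed(path), "line 2")
  path <- bed_file("chr1", c(0, "x"), c(36, 100), c("+", "+"))
  expect_error(read_bed(path), "line 2")
  path <- bed_file("chr1", 0, 36, "*")
  expect_error(read_bed(path), "line 1")
})

test_that("extend_reads anchors at the 5' end and clamps to bounds", {
  genome <- c(chr1 = 1000L)
  gr <- reads_gr("chr1", c(100, 500, 100), c(136, 536, 136),
                 c("+", "-", "-"))
  ext <- extend_reads(gr, genome, extension = 300)
  expect_equal(GenomicRanges::start(ext) - 1L, c(100L, 236L, 0L))
  expect_equal(GenomicRanges::end(ext), c(400L, 536L, 136L))
  # plus-strand read near the chromosome end clamps on the right
  ext2 <- extend_reads(reads_gr("chr1", 900, 936, "+"), genome)
  expect_equal(GenomicRanges::end(ext2), 1000L)
  expect_error(extend_reads(reads_gr("chrX", 0, 36, "+"), genome),
               "absent")
})

test_that("build_coverage counts overlaps and normalizes by depth", {
  genome <- c(chr1 = 2000L)
  frags <- reads_gr("chr1", c(0, 150), c(300, 450), c("+", "+"))
  tr <- build_coverage(frags, genome, bin_width = 1,
                       target_depth = 2, n_reads = 2)  # factor 1
  v <- track_values(tr, "chr1")
  expect_equal(v[201], 2)   # base 200 (0-based) covered by both
  expect_equal(v[100], 1)
  expect_equal(v[500], 0)

  tr2 <- build_coverage(frags, genome, target_depth = 5e7,
                        n_reads = 25e6)
  expect_equal(tr2$normalization_factor, 2)
  expect_equal(tr2$effective_depth, 25e6)
  expect_error(build_coverage(frags, genome, n_reads = 0),
               "normalization")
})

test_that("coverage equals the brute-force per-base counter (randomized)", {
  set.seed(42)
  genome <- c(chrT = 2000L)
  for (rep in 1:5) {
    n <- 50L
    s <- sample(0:1960, n, replace = TRUE)
    e <- s + sample(10:40, n, replace = TRUE)
    st <- sample(c("+", "-"), n, replace = TRUE)
    frags <- extend_reads(reads_gr("chrT", s, e, st), genome)
    tr <- build_coverage(frags, genome, bin_width = 1,
                         target_depth = n, n_reads = n)  # factor 1
    oracle <- brute_coverage(GenomicRanges::start(frags) - 1L,
                             GenomicRanges::end(frags), 2000L)
    expect_equal(track_values(tr, "chrT"), oracle)
  }
})

test_that("track mass conserves clamped fragment bp times the factor", {
  set.seed(7)
  genome <- c(chrT = 5000L)
  s <- sample(0:4990, 80, replace = TRUE)
  reads <- reads_gr("chrT", s, s + 10, sample(c("+", "-"), 80, TRUE))
  frags <- extend_reads(reads, genome)
  frag_bp <- sum(GenomicRanges::width(frags))
  tr1 <- build_coverage(frags, genome, bin_width = 1,
                        target_depth = 5e7, n_reads = 80)
  expect_equal(track_mass(tr1), frag_bp * tr1$normalization_factor)
  # binned track keeps total mass (bin means repeated over full bins;
  # only the truncated last bin can shift mass, absent here)
  tr10 <- build_coverage(frags, genome, bin_width = 10,
                         target_depth = 5e7, n_reads = 80)
  expect_equal(track_mass(tr10), frag_bp * tr1$normalization_factor,
               tolerance = 10 / 5000)
})

test_that("mirroring coordinates and strands mirrors the coverage", {
  set.seed(11)
  G <- 3000L
  genome <- c(chrT = G)
  n <- 60L
  s <- sample(0:2960, n, replace = TRUE)
  e <- s + 36L
  st <- sample(c("+", "-"), n, replace = TRUE)
  fwd <- build_coverage(extend_reads(reads_gr("chrT", s, e, st), genome),
                        genome, bin_width = 1, target_depth = n,
                        n_reads = n)
  mir_st <- ifelse(st == "+", "-", "+")
  mir <- build_coverage(extend_reads(reads_gr("chrT", G - e, G - s, mir_st),
                                     genome),
                        genome, bin_width = 1, target_depth = n,
                        n_reads = n)
  expect_equal(track_values(mir, "chrT"), rev(track_values(fwd, "chrT")))
})

test_that("tracks round-trip through bedGraph and bigWig", {
  genome <- c(chr1 = 300L)
  tr <- manual_track(c(rep(2.5, 100), rep(0, 150), rep(1.25, 50)),
                     chrom = "chr1")
  bg <- tempfile(fileext = ".bedGraph")
  write_track(tr, bg, format = "bedGraph")
  lines <- readLines(bg)
  expect_true("chr1\t0\t100\t2.5" %in% lines)
  expect_false(any(grepl("\t0$", lines)))   # zero runs omitted
  back <- read_track(bg, genome)
  expect_equal(track_values(back, "chr1"), track_values(tr, "chr1"),
               tolerance = 1e-6)

  bw <- tempfile(fileext = ".bw")
  write_track(tr, bw, format = "bigWig")
  back2 <- read_track(bw, genome)
  expect_equal(track_values(back2, "chr1"), track_values(tr, "chr1"),
               tolerance = 1e-6)

  zero <- manual_track(rep(0, 100), chrom = "chr1")
  zf <- tempfile(fileext = ".bedGraph")
  write_track(zero, zf, format = "bedGraph")
  expect_length(readLines(zf), 0L)
})

test_that("deduplication and the make_track wrapper behave as documented", {
  genome <- c(chr1 = 1000L)
  gr <- reads_gr("chr1", c(10, 10, 10, 50), c(46, 46, 46, 86),
                 c("+", "+", "-", "+"))
  expect_length(deduplicate_reads(gr), 3L)  # same interval, both strands kept
  tr <- make_track(gr, genome, extension = 100, bin_width = 1,
                   target_depth = 4, dedup = TRUE)
  # normalisation still uses the raw (pre-dedup) count of 4
  expect_equal(tr$normalization_factor, 1)
})
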