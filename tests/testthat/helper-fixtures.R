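# Shared fixtures: all built in code, no data files.

# GRanges of reads from 0-based half-open coordinates.
reads_gr <- function(chrom, start, end, strand, genome = NULL) {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    seqinfo = if (is.null(genome)) NULL
              else GenomeInfoDb::Seqinfo(names(genome), unname(genome)))
}

# Independent brute-force per-base overlap counter (0-based half-open
# fragments on a single chromosome); the oracle for build_coverage.
brute_coverage <- function(starts, ends, chrom_len) {
  counts <- numeric(chrom_len)
  for (i in seq_along(starts)) {
    s <- max(0L, starts[i])
    e <- min(chrom_len, ends[i])
    if (e > s) counts[(s + 1L):e] <- counts[(s + 1L):e] + 1
  }
  counts
}

# Per-base numeric values of a track chromosome.
track_values <- function(track, chrom) {
  as.numeric(track$values[[chrom]])
}

# Hand-built CoverageTrack from a per-base numeric vector (factor 1).
manual_track <- function(values, chrom = "chrT",
                         normalization_factor = 1, effective_depth = 1) {
  genome <- stats::setNames(length(values), chrom)
  rl <- methods::as(stats::setNames(list(S4Vectors::Rle(values)), chrom),
                    "SimpleRleList")
  structure(list(values = rl, bin_width = 1L,
                 normalization_factor = normalization_factor,
                 effective_depth = effective_depth,
                 seqlengths = pol2wave::genome_table(genome)),
            class = "CoverageTrack")
}

# One-gene panel helper (0-based half-open).
one_gene <- function(start, end, strand = "+", chrom = "chrT", id = "g1") {
  pol2wave::gene_panel(data.frame(id = id, chrom = chrom, strand = strand,
                                  start = start, end = end))
}

# Write a BED6 tempfile from vectors of 0-based coordinates.
bed_file <- function(chrom, start, end, strand, score = 0) {
  path <- tempfile(fileext = ".bed")
  writeLines(paste(chrom, start, end, ".", score, strand, sep = "\t"), path)
  path
}

# Textbook Kruskal-Wallis statistic with tie correction, computed from
# first principles (the oracle for compare_distributions).
kw_statistic <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  n <- length(all)
  rx <- sum(r[seq_along(x)])
  ry <- sum(r[-seq_along(x)])
  h <- 12 / (n * (n + 1)) *
    (rx^2 / length(x) + ry^2 / length(y)) - 3 * (n + 1)
  ties <- table(all)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
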