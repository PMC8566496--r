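# Coverage-track layer: BED input, 5'-anchored fragment extension, and
# depth-normalised coverage.  All user-facing coordinates are 0-based
# half-open (BED convention); GRanges objects used internally are 1-based.

#' Read a chromosome-sizes table
#'
#' Reads the standard two-column `chrom.sizes` text format (chromosome name,
#' length in bp) into a named integer vector, the genome table used
#' throughout the package.
#'
#' @param path Path to a tab-separated two-column file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  genome_table(stats::setNames(tab$length, tab$chrom))
}

#' Validate a genome table
#'
#' A genome table is a named numeric vector mapping chromosome name to
#' length in bp.  Names must be unique and lengths positive integers.
#'
#' @param genome Named numeric vector.
#' @return The validated table as a named integer vector.
#' @export
genome_table <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome table must have chromosome names")
  if (anyDuplicated(names(genome)))
    stop("duplicated chromosome names in genome table")
  if (any(!is.finite(genome)) || any(genome <= 0) || any(genome != floor(genome)))
    stop("chromosome lengths must be positive integers")
  stats::setNames(as.integer(genome), names(genome))
}

.seqinfo_from_genome <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = unname(genome))
}

#' Read aligned reads from a BED6 file
#'
#' Parses a BED file with at least six tab-separated fields (chrom, start,
#' end, name, score, strand) into a strand-annotated `GRanges`.  Input
#' coordinates are 0-based half-open and are converted to the 1-based
#' convention of `GRanges`.  Malformed lines (non-integer coordinates,
#' start >= end, strand other than `+`/`-`) raise an error naming the first
#' offending line.
#'
#' @param path Path to a BED6 file.
#' @param genome Optional genome table; when given, the returned object
#'   carries the corresponding `seqinfo` and reads on unknown chromosomes
#'   are an error.
#' @return `GRanges` of reads, in file order.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  empty <- GenomicRanges::GRanges(
    seqinfo = if (is.null(genome)) GenomeInfoDb::Seqinfo()
              else .seqinfo_from_genome(genome))
  if (file.size(path) == 0) return(empty)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 6)
    stop("BED6 required (>= 6 tab-separated fields): ", path)
  s <- suppressWarnings(as.numeric(tab[[2]]))
  e <- suppressWarnings(as.numeric(tab[[3]]))
  st <- tab[[6]]
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e) |
    s < 0 | e <= s | !(st %in% c("+", "-"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed BED line %d in %s: '%s'", i, path,
                 paste(unlist(tab[i, 1:6]), collapse = "\t")))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(tab[[1]]), names(genome))
    if (length(unknown))
      stop("reads on chromosomes absent from genome table: ",
           paste(unknown, collapse = ", "))
  }
  GenomicRanges::GRanges(
    tab[[1]], IRanges::IRanges(start = as.integer(s) + 1L, end = as.integer(e)),
    strand = st,
    seqinfo = if (is.null(genome)) NULL else .seqinfo_from_genome(genome))
}

#' Write reads to a BED6 file
#'
#' Inverse of [read_bed()]: writes a strand-annotated `GRanges` as BED6
#' (0-based half-open), with `.` name and score 0.
#'
#' @param reads `GRanges` of reads.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(reads, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                   start = GenomicRanges::start(reads) - 1L,
                   end = GenomicRanges::end(reads),
                   name = ".", score = 0L,
                   strand = as.character(GenomicRanges::strand(reads)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove exact duplicate reads
#'
#' Optional clonal-read filter: drops reads identical in chromosome, start,
#' end and strand, keeping one copy.  Upstream pipelines usually remove
#' duplicates before this package sees the data.
#'
#' @param reads `GRanges` of reads.
#' @return Deduplicated `GRanges`.
#' @export
deduplicate_reads <- function(reads) {
  unique(reads)
}

#' Extend reads into fixed-length fragments from their 5' ends
#'
#' Each read is replaced by a fragment of length `extension` anchored at the
#' read's 5' end and oriented 5' to 3' along its strand: a plus-strand read
#' starting at `s` (0-based) becomes `[s, s + extension)`, a minus-strand
#' read ending at `e` becomes `[e - extension, e)`.  Fragments are clamped
#' to chromosome bounds.  This emulates replacing the sequenced read by the
#' ChIP library fragment it tags (default 300 bp).
#'
#' @param reads `GRanges` of reads.
#' @param genome Genome table (named lengths); every read chromosome must be
#'   present.
#' @param extension Fragment length in bp (default 300).
#' @return `GRanges` of extended fragments carrying the genome `seqinfo`.
#' @export
extend_reads <- function(reads, genome, extension = 300L) {
  genome <- genome_table(genome)
  stopifnot(length(extension) == 1L, extension > 0)
  chr <- as.character(GenomicRanges::seqnames(reads))
  unknown <- setdiff(unique(chr), names(genome))
  if (length(unknown))
    stop("read chromosome(s) absent from genome table: ",
         paste(unknown, collapse = ", "))
  len <- unname(genome[chr])
  plus <- as.character(GenomicRanges::strand(reads)) == "+"
  s1 <- GenomicRanges::start(reads)   # 1-based
  e1 <- GenomicRanges::end(reads)
  new_s <- ifelse(plus, s1, pmax(e1 - as.integer(extension) + 1L, 1L))
  new_e <- ifelse(plus, pmin(s1 + as.integer(extension) - 1L, len), e1)
  GenomicRanges::GRanges(chr, IRanges::IRanges(start = new_s, end = new_e),
                         strand = GenomicRanges::strand(reads),
                         seqinfo = .seqinfo_from_genome(genome))
}

#' Build a depth-normalised coverage track
#'
#' Counts, per base, the extended fragments overlapping it, scales by
#' `target_depth / n_reads` so that libraries of different sizes are
#' comparable (default target 50 million reads), and averages within
#' fixed-width bins.  The track stores per-nucleotide values (bin means
#' repeated across each bin), so downstream statistics are always computed
#' on per-nucleotide densities.
#'
#' @param reads `GRanges` of already-extended fragments (see
#'   [extend_reads()]).
#' @param genome Genome table.
#' @param bin_width Bin width in bp (default 10); 1 keeps exact per-base
#'   counts.
#' @param target_depth Read depth all libraries are scaled to (default
#'   5e7).
#' @param n_reads Raw aligned-read count used for normalisation; defaults
#'   to `length(reads)`.  Pass the pre-filter count if reads were dropped
#'   after alignment.
#' @return A `CoverageTrack` object: list with elements `values` (an
#'   `RleList` of per-base normalised densities), `bin_width`,
#'   `normalization_factor`, `effective_depth` and `seqlengths`.
#' @export
build_coverage <- function(reads, genome, bin_width = 10L,
                           target_depth = 5e7, n_reads = length(reads)) {
  genome <- genome_table(genome)
  stopifnot(bin_width >= 1, target_depth > 0)
  if (n_reads <= 0)
    stop("normalization undefined: raw read count must be > 0")
  si <- .seqinfo_from_genome(genome)
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(reads)),
    IRanges::IRanges(GenomicRanges::start(reads), GenomicRanges::end(reads)),
    seqinfo = si)
  cov <- GenomicRanges::coverage(gr)
  factor <- target_depth / n_reads
  cov <- cov * factor
  bin_width <- as.integer(bin_width)
  if (bin_width > 1L) {
    cov <- methods::as(lapply(cov, .bin_average_rle, bw = bin_width),
                       "SimpleRleList")
  }
  structure(list(values = cov,
                 bin_width = bin_width,
                 normalization_factor = factor,
                 effective_depth = n_reads,
                 seqlengths = genome),
            class = "CoverageTrack")
}

# Average an Rle in fixed-width bins and re-expand to per-base runs.
.bin_average_rle <- function(x, bw) {
  n <- length(x)
  starts <- seq.int(1L, n, by = bw)
  w <- pmin(bw, n - starts + 1L)
  m <- IRanges::viewMeans(IRanges::Views(x, start = starts, width = w))
  S4Vectors::Rle(as.numeric(m), w)
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$values), "chromosome(s),",
      "bin width", x$bin_width, "bp\n")
  cat("  effective depth:", x$effective_depth,
      " normalization factor:", format(x$normalization_factor), "\n")
  invisible(x)
}

#' Total signal mass of a track
#'
#' Sum of per-base densities over the genome, i.e. normalised
#' fragment-base mass.  At `bin_width = 1` this equals the clamped
#' extended-fragment bp total times the normalisation factor exactly.
#'
#' @param track A `CoverageTrack`.
#' @return Numeric scalar.
#' @export
track_mass <- function(track) {
  sum(vapply(track$values, function(r) sum(as.numeric(runValue(r)) *
                                             runLength(r)), numeric(1)))
}

#' Write a coverage track to bedGraph or bigWig
#'
#' Zero-density runs are omitted (sparse run-length form), so an all-zero
#' track yields a file with no intervals.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param format `"bedGraph"` or `"bigWig"`.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path, format = c("bedGraph", "bigWig")) {
  format <- match.arg(format)
  gr <- methods::as(track$values, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  GenomeInfoDb::seqlengths(gr) <- unname(track$seqlengths[GenomeInfoDb::seqlevels(gr)])
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read a coverage track from bedGraph or bigWig
#'
#' Rebuilds the per-base `RleList` representation from a file written with
#' [write_track()] (or any bedGraph/bigWig).  Bases not covered by any
#' interval get density 0.
#'
#' @param path Input path.
#' @param genome Genome table giving chromosome lengths.
#' @param format `"bedGraph"` or `"bigWig"`; guessed from the extension by
#'   default.
#' @return A `CoverageTrack` (with `NA` normalisation metadata, which is
#'   not stored in these formats).
#' @export
read_track <- function(path, genome, format = NULL) {
  genome <- genome_table(genome)
  gr <- if (is.null(format)) rtracklayer::import(path)
        else rtracklayer::import(path, format = format)
  si <- .seqinfo_from_genome(genome)
  gr2 <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)),
                                seqinfo = si)
  cov <- GenomicRanges::coverage(gr2, weight = S4Vectors::mcols(gr)$score)
  structure(list(values = cov, bin_width = 1L,
                 normalization_factor = NA_real_,
                 effective_depth = NA_real_,
                 seqlengths = genome),
            class = "CoverageTrack")
}

#' Mean per-nucleotide density over an interval
#'
#' Average of the track's per-base normalised density over a 0-based
#' half-open genomic interval, clamped to chromosome bounds.
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Numeric scalar.
#' @export
mean_density <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$seqlengths))
    stop("unknown chromosome: ", chrom)
  len <- track$seqlengths[[chrom]]
  s <- max(0, start)
  e <- min(len, end)
  if (s >= e) stop("empty interval after clamping: [", start, ", ", end, ")")
  mean(S4Vectors::window(track$values[[chrom]], s + 1L, e))
}

#' One-call track construction from raw reads
#'
#' Convenience wrapper chaining [extend_reads()] and [build_coverage()],
#' normalising by the raw (pre-extension) read count.
#'
#' @inheritParams extend_reads
#' @inheritParams build_coverage
#' @param dedup Drop exact duplicate reads before extension (default
#'   `FALSE`; the raw count used for normalisation is taken before
#'   deduplication).
#' @return A `CoverageTrack`.
#' @export
make_track <- function(reads, genome, extension = 300L, bin_width = 10L,
                       target_depth = 5e7, dedup = FALSE) {
  n_raw <- length(reads)
  if (dedup) reads <- deduplicate_reads(reads)
  frags <- extend_reads(reads, genome, extension = extension)
  build_coverage(frags, genome, bin_width = bin_width,
                 target_depth = target_depth, n_reads = n_raw)
}
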