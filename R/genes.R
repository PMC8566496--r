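# Gene models and the strand-aware three-region bin scheme.
#
# Gene coordinates are 0-based half-open [start, end).  The transcription
# start site (TSS) is `start` on the plus strand and `end` on the minus
# strand; the termination site (TTS) is the opposite end.  Each gene is
# divided into a 5'-end bin [TSS-50, TSS+200), a gene-body bin
# [TSS+200, TTS-500) and a 3'-end bin [TTS-500, TTS+500), all in
# transcription coordinates and reflected onto the genome for minus-strand
# genes.  The body bin is non-empty only for genes longer than 700 bp.

# Offsets of the three-region scheme, bp in transcription coordinates.
.BIN_5P_UP <- 50L     # 5' bin reaches this far upstream of the TSS
.BIN_5P_DOWN <- 200L  # ... and this far downstream
.BIN_3P_FLANK <- 500L # 3' bin extends this far on both sides of the TTS
.MIN_GENE_LENGTH <- 701L

#' Construct a validated gene panel
#'
#' Builds the gene table used by all downstream statistics from a
#' data frame with columns `id`, `chrom`, `strand`, `start`, `end`
#' (0-based half-open).  Genes on chromosomes absent from `genome` and
#' genes too short for a non-empty gene-body bin are dropped with a
#' message stating the counts.
#'
#' @param df Data frame with columns `id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @param genome Optional genome table; enables the unknown-chromosome
#'   filter.
#' @param min_length Minimum gene length kept, in bp (default 701; genes
#'   with `end - start <= min_length` are dropped, which guarantees a
#'   non-empty body bin).
#' @return Data frame with columns `id`, `chrom`, `strand`, `start`,
#'   `end`, `length`, `tss`, `tts`.
#' @export
gene_panel <- function(df, genome = NULL, min_length = .MIN_GENE_LENGTH) {
  need <- c("id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyDuplicated(df$id))
    stop("duplicate gene ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("gene coordinates must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    genome <- genome_table(genome)
    unknown <- !(df$chrom %in% names(genome))
    if (any(unknown)) {
      message(sum(unknown), " gene(s) dropped: unknown chromosome")
      df <- df[!unknown, , drop = FALSE]
    }
  }
  len <- df$end - df$start
  short <- len <= min_length
  if (any(short)) {
    message(sum(short), " gene(s) dropped: length <= ", min_length, " bp")
    df <- df[!short, , drop = FALSE]
    len <- len[!short]
  }
  df$length <- len
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  rownames(df) <- NULL
  df
}

#' Load a gene panel from a tab-separated file
#'
#' Reads a 5-column TSV (`id`, `chrom`, `strand`, `start`, `end`; header
#' optional) or a BED6 file (the `name` field becomes the id) and applies
#' the [gene_panel()] filters.
#'
#' @param path Path to the gene file.
#' @inheritParams gene_panel
#' @return A gene panel data frame (see [gene_panel()]).
#' @export
load_genes <- function(path, genome = NULL, min_length = .MIN_GENE_LENGTH) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- any(c("id", "chrom") %in% fields)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = "character", quote = "",
                           comment.char = "")
  df <- if (!has_header && ncol(tab) >= 6 &&
            all(tab[[6]] %in% c("+", "-"))) {
    # BED6: chrom start end name score strand
    data.frame(id = tab[[4]], chrom = tab[[1]], strand = tab[[6]],
               start = tab[[2]], end = tab[[3]])
  } else {
    if (!has_header) names(tab)[1:5] <- c("id", "chrom", "strand",
                                          "start", "end")
    tab[, c("id", "chrom", "strand", "start", "end")]
  }
  gene_panel(df, genome = genome, min_length = min_length)
}

#' Write a gene panel to TSV
#'
#' @param genes Gene panel data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("id", "chrom", "strand", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Three-region bin boundaries for a gene panel
#'
#' Vectorised computation of the genomic intervals (0-based half-open) of
#' the 5'-end, gene-body and 3'-end bins for every gene, reflected for
#' minus-strand genes.  When a genome table is supplied, bins are clamped
#' to chromosome bounds; a gene whose 5' bin is emptied by clamping is
#' marked invalid.
#'
#' @param genes Gene panel data frame.
#' @param genome Optional genome table for clamping.
#' @return Data frame with columns `id`, `chrom`, `strand`, `five_start`,
#'   `five_end`, `body_start`, `body_end`, `three_start`, `three_end`,
#'   `valid`.
#' @export
gene_bins <- function(genes, genome = NULL) {
  plus <- genes$strand == "+"
  tss <- genes$tss
  tts <- genes$tts
  five_s <- ifelse(plus, tss - .BIN_5P_UP, tss - .BIN_5P_DOWN)
  five_e <- ifelse(plus, tss + .BIN_5P_DOWN, tss + .BIN_5P_UP)
  body_s <- ifelse(plus, tss + .BIN_5P_DOWN, tts + .BIN_3P_FLANK)
  body_e <- ifelse(plus, tts - .BIN_3P_FLANK, tss - .BIN_5P_DOWN)
  three_s <- tts - .BIN_3P_FLANK
  three_e <- tts + .BIN_3P_FLANK
  out <- data.frame(id = genes$id, chrom = genes$chrom,
                    strand = genes$strand,
                    five_start = five_s, five_end = five_e,
                    body_start = body_s, body_end = body_e,
                    three_start = three_s, three_end = three_e)
  if (!is.null(genome)) {
    genome <- genome_table(genome)
    len <- unname(genome[out$chrom])
    for (p in c("five", "body", "three")) {
      out[[paste0(p, "_start")]] <- pmax(out[[paste0(p, "_start")]], 0)
      out[[paste0(p, "_end")]] <- pmin(out[[paste0(p, "_end")]], len)
    }
  }
  out$valid <- out$five_end > out$five_start &
    out$body_end > out$body_start &
    out$three_end > out$three_start
  out
}

#' Three-region bin scheme for a single gene
#'
#' @param gene One-row gene panel data frame (or a list with fields `id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `tts`, `length`).
#' @param genome Optional genome table for clamping.
#' @return List with elements `five_prime`, `body`, `three_prime` (each a
#'   length-2 numeric `c(start, end)`, 0-based half-open), plus `chrom`
#'   and `strand`.
#' @export
bin_scheme <- function(gene, genome = NULL) {
  gene <- as.data.frame(gene)
  if (nrow(gene) != 1L) stop("bin_scheme() expects a single gene")
  if (gene$length <= 700)
    stop("gene '", gene$id, "' too short for a non-empty body bin (",
         gene$length, " bp <= 700 bp)")
  b <- gene_bins(gene, genome = genome)
  list(five_prime = c(b$five_start, b$five_end),
       body = c(b$body_start, b$body_end),
       three_prime = c(b$three_start, b$three_end),
       chrom = b$chrom, strand = b$strand)
}
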