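# Promoter-proximal pausing and 3' release statistics.
#
# For each gene the mean per-nucleotide density is computed over the three
# bins of the scheme in genes.R.  The 5' pausing ratio is the 5'-end bin
# density over the gene-body density; the 3' release ratio is the 3'-end
# bin density over the gene-body density.  A gene with zero body density
# has undefined ratios and is flagged invalid rather than given a
# pseudocount.

#' Pausing and release ratios per gene
#'
#' Computes the mean per-nucleotide density in the 5'-end, gene-body and
#' 3'-end bins of each gene and the derived 5' pausing ratio
#' (`pr5 = d5 / dbody`) and 3' release ratio (`rr3 = d3 / dbody`).  Both
#' ratios are invariant under any global rescaling of the track, in
#' particular under the depth normalisation.  Genes with zero body density
#' (or with bins emptied by chromosome-bound clamping) have `valid =
#' FALSE` and `NA` ratios.
#'
#' @param track A `CoverageTrack`.
#' @param genes Gene panel data frame (see [gene_panel()]).
#' @return Data frame with columns `gene`, `d5`, `dbody`, `d3`, `pr5`,
#'   `rr3`, `valid`.
#' @export
pausing_ratios <- function(track, genes) {
  bins <- gene_bins(genes, genome = track$seqlengths)
  n <- nrow(bins)
  d5 <- dbody <- d3 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!bins$valid[i]) next
    d5[i] <- mean_density(track, bins$chrom[i], bins$five_start[i],
                          bins$five_end[i])
    dbody[i] <- mean_density(track, bins$chrom[i], bins$body_start[i],
                             bins$body_end[i])
    d3[i] <- mean_density(track, bins$chrom[i], bins$three_start[i],
                          bins$three_end[i])
  }
  valid <- bins$valid & !is.na(dbody) & dbody > 0
  pr5 <- ifelse(valid, d5 / dbody, NA_real_)
  rr3 <- ifelse(valid, d3 / dbody, NA_real_)
  data.frame(gene = bins$id, d5 = d5, dbody = dbody, d3 = d3,
             pr5 = pr5, rr3 = rr3, valid = valid)
}

#' Pausing-ratio table across time points and conditions
#'
#' Applies [pausing_ratios()] to each track of a time course and stacks
#' the results into one long table with one row per (gene, time point,
#' condition).  Sorted-ratio curves (rank versus 5' pausing ratio, valid
#' genes only) are attached as the `"curves"` attribute for plotting.
#'
#' @param tracks List of `CoverageTrack` objects.
#' @param genes Gene panel data frame.
#' @param meta Data frame with one row per track and columns `time` and
#'   `condition`.
#' @return Long data frame with columns `gene`, `time`, `condition`,
#'   `d5`, `dbody`, `d3`, `pr5`, `rr3`, `valid`; attribute `"curves"` is a
#'   list (one element per track) of sorted `pr5` values.
#' @export
ratio_table <- function(tracks, genes, meta) {
  stopifnot(length(tracks) >= 1L, nrow(genes) >= 1L)
  if (!is.data.frame(meta) || nrow(meta) != length(tracks) ||
      !all(c("time", "condition") %in% names(meta)))
    stop("meta must be a data frame with one row per track and columns ",
         "'time' and 'condition'")
  pieces <- vector("list", length(tracks))
  curves <- vector("list", length(tracks))
  n_invalid <- 0L
  for (k in seq_along(tracks)) {
    r <- pausing_ratios(tracks[[k]], genes)
    r$time <- meta$time[k]
    r$condition <- meta$condition[k]
    pieces[[k]] <- r[, c("gene", "time", "condition", "d5", "dbody", "d3",
                         "pr5", "rr3", "valid")]
    curves[[k]] <- sort(r$pr5[r$valid])
    n_invalid <- n_invalid + sum(!r$valid)
  }
  names(curves) <- paste(meta$condition, meta$time, sep = "_t")
  if (n_invalid > 0)
    message(n_invalid, " (gene, track) pair(s) excluded from sorted ",
            "curves: undefined ratio")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Plot sorted pausing-ratio curves
#'
#' Rank-versus-value curves of the 5' pausing ratio, one line per track,
#' as attached by [ratio_table()].
#'
#' @param tbl Output of [ratio_table()].
#' @param log Use a log-scaled ratio axis (default `TRUE`).
#' @param ... Passed to [graphics::matplot()]-style plotting.
#' @return Invisibly, `NULL`.
#' @export
plot_sorted_ratios <- function(tbl, log = TRUE, ...) {
  curves <- attr(tbl, "curves")
  if (is.null(curves) || !length(curves)) {
    keys <- paste(tbl$condition, tbl$time, sep = "_t")
    curves <- lapply(split(tbl[tbl$valid, "pr5"], keys[tbl$valid]), sort)
  }
  cols <- grDevices::hcl.colors(length(curves), "Dark 3")
  ylim <- range(unlist(curves), finite = TRUE)
  graphics::plot(NA, xlim = c(0, 1), ylim = ylim,
                 log = if (log) "y" else "",
                 xlab = "gene rank (fraction)", ylab = "5' pausing ratio",
                 ...)
  for (k in seq_along(curves)) {
    y <- curves[[k]]
    graphics::lines(seq_along(y) / length(y), y, col = cols[k])
  }
  graphics::legend("topleft", legend = names(curves), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(NULL)
}
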