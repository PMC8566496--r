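# Scaled metagene profiles and promoter-density time-course statistics.

# Per-base track values over [start, end) (0-based half-open), reversed
# for minus-strand genes so that the vector runs 5' -> 3' in
# transcription orientation.
.track_slice <- function(track, chrom, start, end, minus = FALSE) {
  v <- as.numeric(S4Vectors::window(track$values[[chrom]], start + 1L, end))
  if (minus) rev(v) else v
}

# Means over `nbins` equal-width sub-intervals of a numeric vector
# (boundaries floor(i * n / nbins)).
.rescale_means <- function(v, nbins) {
  n <- length(v)
  bounds <- floor(seq_len(nbins) * n / nbins)
  cs <- c(0, cumsum(v))
  lo <- c(0, bounds[-nbins])
  (cs[bounds + 1L] - cs[lo + 1L]) / (bounds - lo)
}

#' Scaled metagene profile
#'
#' Averages track density across genes after rescaling each gene body
#' (TSS to TTS) to a fixed number of bins; upstream and downstream flanks
#' are kept at absolute bp resolution.  Minus-strand genes are traversed
#' 5' to 3', so the profile is in transcription orientation.  Genes whose
#' flanked window extends beyond their chromosome are dropped with a
#' message.
#'
#' @param track A `CoverageTrack`.
#' @param genes Gene panel data frame.
#' @param body_bins Number of bins the gene body is rescaled to (default
#'   100, minimum 10).
#' @param flank Flank length in bp on each side (default 2000).
#' @param flank_bin Flank resolution in bp (default 50; must divide
#'   `flank`).
#' @return A `MetageneProfile`: list with `values` (mean density per
#'   position), `region` (factor `upstream`/`body`/`downstream`),
#'   `position` (bp for flanks, bin index for the body), `n_genes`,
#'   `body_bins`, `flank`, `flank_bin`.
#' @export
scaled_metagene <- function(track, genes, body_bins = 100L, flank = 2000L,
                            flank_bin = 50L) {
  if (nrow(genes) == 0L) stop("empty gene list")
  stopifnot(body_bins >= 10L, flank > 0, flank %% flank_bin == 0)
  fb <- as.integer(flank / flank_bin)
  total <- numeric(2L * fb + body_bins)
  n_used <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- track$seqlengths[[g$chrom]]
    ws <- min(g$start, g$end) - flank
    we <- max(g$start, g$end) + flank
    if (ws < 0 || we > len) next
    v <- .track_slice(track, g$chrom, ws, we, minus = g$strand == "-")
    up <- .rescale_means(v[seq_len(flank)], fb)
    body <- .rescale_means(v[(flank + 1L):(flank + g$length)], body_bins)
    down <- .rescale_means(v[(flank + g$length + 1L):length(v)], fb)
    total <- total + c(up, body, down)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no gene with a full flanked window on its chromosome")
  if (n_used < nrow(genes))
    message(nrow(genes) - n_used, " gene(s) dropped from metagene: ",
            "flanked window off chromosome")
  structure(list(
    values = total / n_used,
    region = factor(rep(c("upstream", "body", "downstream"),
                        c(fb, body_bins, fb)),
                    levels = c("upstream", "body", "downstream")),
    position = c(seq(-flank, -flank_bin, by = flank_bin),
                 seq_len(body_bins),
                 seq(0, flank - flank_bin, by = flank_bin)),
    n_genes = n_used, body_bins = as.integer(body_bins),
    flank = as.integer(flank), flank_bin = as.integer(flank_bin)),
    class = "MetageneProfile")
}

#' Anchored (unscaled) average profile
#'
#' Average density in transcription orientation over a fixed window
#' centred on the TSS or TTS of each gene, without body rescaling.
#'
#' @param track A `CoverageTrack`.
#' @param genes Gene panel data frame.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param window Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 50; must divide `window`).
#' @return A `MetageneProfile` with positions in bp relative to the
#'   anchor.
#' @export
anchor_profile <- function(track, genes, anchor = c("TSS", "TTS"),
                           window = 2000L, bin = 50L) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("empty gene list")
  stopifnot(window > 0, window %% bin == 0)
  nb <- as.integer(2L * window / bin)
  total <- numeric(nb)
  n_used <- 0L
  pos0 <- if (anchor == "TSS") genes$tss else genes$tts
  for (i in seq_len(nrow(genes))) {
    len <- track$seqlengths[[genes$chrom[i]]]
    minus <- genes$strand[i] == "-"
    ws <- pos0[i] - window
    we <- pos0[i] + window
    if (ws < 0 || we > len) next
    v <- .track_slice(track, genes$chrom[i], ws, we, minus = minus)
    total <- total + .rescale_means(v, nb)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no gene with a full anchored window on its chromosome")
  structure(list(
    values = total / n_used,
    region = factor(rep(anchor, nb), levels = anchor),
    position = seq(-window, window - bin, by = bin),
    n_genes = n_used, body_bins = 0L,
    flank = as.integer(window), flank_bin = as.integer(bin)),
    class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile:", length(x$values), "positions,",
      x$n_genes, "genes\n")
  invisible(x)
}

#' @export
as.data.frame.MetageneProfile <- function(x, ...) {
  data.frame(region = x$region, position = x$position,
             density = x$values, n_genes = x$n_genes)
}

#' @export
plot.MetageneProfile <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "position bin", ylab = "mean density",
                 ...)
  edges <- cumsum(table(x$region))
  graphics::abline(v = edges[-length(edges)] + 0.5, lty = 3)
  invisible(NULL)
}

#' Promoter-density series over a time course
#'
#' Per-gene mean density of the promoter region (the 5'-end bin,
#' [TSS-50, TSS+200) in transcription coordinates) at each time point of
#' one condition, with a per-time-point central statistic.  Genes whose
#' 5' bin is invalid are excluded; because validity depends only on the
#' gene geometry, the gene set is identical at every time point.
#'
#' @param tracks List of `CoverageTrack` objects, one per time point
#'   (at least 2).
#' @param genes Gene panel data frame.
#' @param times Numeric time points (minutes), defaulting to
#'   `as.numeric(names(tracks))`.
#' @return A `PromoterSeries`: list with `times`, `densities` (genes x
#'   times matrix), `medians`, `means`, `gene_ids`.
#' @export
promoter_series <- function(tracks, genes, times = NULL) {
  if (is.null(times)) times <- as.numeric(names(tracks))
  if (length(tracks) < 2L) stop("at least 2 time points required")
  if (length(times) != length(tracks) || any(is.na(times)))
    stop("times must be numeric, one per track")
  bins <- gene_bins(genes, genome = tracks[[1]]$seqlengths)
  keep <- bins$valid
  if (!any(keep)) stop("no gene with a valid promoter bin")
  if (any(!keep))
    message(sum(!keep), " gene(s) excluded from promoter series: ",
            "invalid bins")
  bins <- bins[keep, , drop = FALSE]
  dens <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(bins)), function(i)
      mean_density(tr, bins$chrom[i], bins$five_start[i], bins$five_end[i]),
      numeric(1))
  }, numeric(nrow(bins)))
  dens <- matrix(dens, nrow = nrow(bins),
                 dimnames = list(bins$id, paste0("t", times)))
  structure(list(times = times, densities = dens,
                 medians = apply(dens, 2, stats::median),
                 means = colMeans(dens),
                 gene_ids = bins$id),
            class = "PromoterSeries")
}

#' @export
print.PromoterSeries <- function(x, ...) {
  cat("PromoterSeries:", length(x$gene_ids), "genes,",
      length(x$times), "time points\n")
  print(data.frame(time = x$times, median = unname(x$medians),
                   mean = unname(x$means)))
  invisible(x)
}

#' Percent decrease of promoter density between two time points
#'
#' `100 * (1 - central(t1) / central(t0))` where the central statistic is
#' the per-time-point median (or mean).  Negative values indicate an
#' increase.  The result is invariant under a global rescaling applied
#' equally to both time points.
#'
#' @param series A `PromoterSeries`.
#' @param t0,t1 Time points present in the series.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Percent decrease (numeric scalar).
#' @export
percent_decrease <- function(series, t0, t1, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  central <- if (stat == "median") series$medians else series$means
  i0 <- match(t0, series$times)
  i1 <- match(t1, series$times)
  if (is.na(i0) || is.na(i1))
    stop("time point(s) not in series: ",
         paste(c(t0, t1)[is.na(c(i0, i1))], collapse = ", "))
  if (central[i0] == 0)
    stop("central statistic at t0 = ", t0, " is zero; percent decrease ",
         "undefined")
  unname(100 * (1 - central[i1] / central[i0]))
}

#' Rank-based comparison of promoter densities between conditions
#'
#' Kruskal-Wallis one-way analysis of variance on ranks comparing the
#' per-gene promoter densities of two series at one time point (the
#' two-group case of ANOVA on ranks).
#'
#' @param series_a,series_b `PromoterSeries` objects containing `time`.
#' @param time Time point to compare.
#' @return List with `statistic` (chi-squared, tie-corrected), `df`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(series_a, series_b, time) {
  ia <- match(time, series_a$times)
  ib <- match(time, series_b$times)
  if (is.na(ia) || is.na(ib))
    stop("time point ", time, " not present in both series")
  xa <- series_a$densities[, ia]
  xb <- series_b$densities[, ib]
  if (length(xa) < 3L || length(xb) < 3L)
    stop("fewer than 3 genes per condition")
  kt <- stats::kruskal.test(list(a = xa, b = xb))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n_a = length(xa), n_b = length(xb))
}
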