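# Wave-front tracking and kinetic summaries of block/washout time courses.
#
# The wave-front statistic locates, within the gene-body bin, the position
# at which the 5'->3' cumulative density first reaches a given fraction of
# the total body mass.  A high quantile (default 0.9) tracks the leading
# edge of the "emerging wave" of newly released polymerase after drug
# washout; a low quantile (default 0.1) tracks the trailing edge of the
# "retreating wave" during the block.  Regressing the per-time median
# front against time gives an elongation-rate estimate in bp/min.

# Position (1-based offset into the window) where the cumulative mass of
# an Rle first reaches `q` of its total; NA if the total mass is zero.
# Works on runs, so it is exact at per-base resolution but O(#runs).
.cum_quantile_pos <- function(r, q) {
  rv <- as.numeric(S4Vectors::runValue(r))
  rl <- S4Vectors::runLength(r)
  mass <- rv * rl
  total <- sum(mass)
  if (total <= 0) return(NA_real_)
  target <- q * total
  cm <- cumsum(mass)
  i <- which(cm >= target)[1L]
  before <- if (i > 1L) cm[i - 1L] else 0
  k <- ceiling((target - before) / rv[i])
  k <- max(k, 1)
  sum(rl[seq_len(i - 1L)]) + k
}

#' Wave-front position within a gene body
#'
#' Position, in bp downstream of the TSS, at which the cumulative
#' gene-body density accumulated 5' to 3' first reaches `quantile` of the
#' total body mass.  Invariant under global track rescaling and monotone
#' non-decreasing in the quantile.
#'
#' @param track A `CoverageTrack`.
#' @param gene One-row gene panel data frame.
#' @param quantile Mass fraction in (0, 1); 0.9 (default) tracks the
#'   leading edge, 0.1 the trailing edge.
#' @return Position in bp from the TSS (transcription coordinates).
#' @export
wave_front <- function(track, gene, quantile = 0.9) {
  p <- wave_fronts(track, gene, quantile = quantile)
  if (is.na(p)) stop("zero gene-body signal mass for gene '", gene$id, "'")
  unname(p)
}

#' Wave-front positions for a gene panel
#'
#' Vectorised [wave_front()]; genes with zero body mass get `NA`.
#'
#' @inheritParams wave_front
#' @param genes Gene panel data frame.
#' @return Named numeric vector of positions (bp from TSS), `NA` where the
#'   body mass is zero or the bins are invalid.
#' @export
wave_fronts <- function(track, genes, quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  bins <- gene_bins(genes, genome = track$seqlengths)
  out <- rep(NA_real_, nrow(bins))
  for (i in seq_len(nrow(bins))) {
    if (!bins$valid[i]) next
    r <- S4Vectors::window(track$values[[bins$chrom[i]]],
                           bins$body_start[i] + 1L, bins$body_end[i])
    if (bins$strand[i] == "-") r <- rev(r)
    k <- .cum_quantile_pos(r, quantile)
    # body starts 200 bp downstream of the TSS; k is 1-based within it
    if (!is.na(k)) out[i] <- 200 + k - 1
  }
  stats::setNames(out, bins$id)
}

#' Elongation rate from wave-front positions over time
#'
#' Ordinary least-squares fit of front position (bp) against time (min);
#' the slope is the apparent elongation velocity.
#'
#' @param fronts Data frame with columns `time` (min) and `position` (bp),
#'   e.g. per-time medians of [wave_fronts()]; rows with `NA` position are
#'   dropped.
#' @return A `RateFit`: list with `rate` (bp/min), `intercept` (bp),
#'   `residual_sd` (bp), `n`.
#' @export
elongation_rate <- function(fronts) {
  fronts <- fronts[!is.na(fronts$position) & !is.na(fronts$time), ,
                   drop = FALSE]
  if (nrow(fronts) < 2L || length(unique(fronts$time)) < 2L)
    stop("elongation rate needs >= 2 distinct time points")
  fit <- stats::lm(position ~ time, data = fronts)
  res <- stats::residuals(fit)
  structure(list(rate = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 residual_sd = sqrt(mean(res^2)),
                 n = nrow(fronts)),
            class = "RateFit")
}

#' @export
print.RateFit <- function(x, ...) {
  cat(sprintf("RateFit: %.1f bp/min (intercept %.0f bp, rms residual %.0f bp, n = %d)\n",
              x$rate, x$intercept, x$residual_sd, x$n))
  invisible(x)
}

#' Median gene-body density baseline
#'
#' Median across genes of the mean gene-body-bin density of one track,
#' used to scale the recycling index.
#'
#' @param track A `CoverageTrack`.
#' @param genes Gene panel data frame.
#' @return Numeric scalar.
#' @export
body_baseline <- function(track, genes) {
  r <- pausing_ratios(track, genes)
  stats::median(r$dbody, na.rm = TRUE)
}

#' Promoter re-accumulation (recycling) index during drug block
#'
#' Summary of terminated polymerase returning to promoters while pause
#' release is blocked: the least-squares slope of the median promoter
#' density over block time, divided by a baseline gene-body density.  This
#' index is a package-defined summary statistic, not a literature
#' standard; it is reported with that label in [condition_report()]
#' output.
#'
#' @param series A `PromoterSeries` over block time points.
#' @param baseline Initial median gene-body density (see
#'   [body_baseline()]); must be > 0.
#' @return A `RecyclingIndex`: list with `slope` (density/min),
#'   `baseline` (density) and `index` (1/min).
#' @export
recycling_index <- function(series, baseline) {
  if (length(series$times) < 2L)
    stop("recycling index needs >= 2 block time points")
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline gene-body density must be > 0")
  fit <- stats::lm(m ~ t, data = data.frame(t = series$times,
                                            m = unname(series$medians)))
  slope <- unname(coef(fit)[2])
  structure(list(slope = slope, baseline = baseline,
                 index = slope / baseline),
            class = "RecyclingIndex")
}

#' @export
print.RecyclingIndex <- function(x, ...) {
  cat(sprintf("RecyclingIndex: %.4g /min (slope %.4g density/min over baseline %.4g)\n",
              x$index, x$slope, x$baseline))
  cat("  (package-defined promoter re-accumulation summary)\n")
  invisible(x)
}

#' Analyse one condition of a block/washout time course
#'
#' Runs the full statistics stack on the tracks of one condition: the
#' pausing-ratio table, promoter-density series for the block and washout
#' phases, the recycling index over the block, the washout promoter
#' percent decrease, and the emerging-wave elongation-rate fit over the
#' washout samples.
#'
#' @param tracks List of `CoverageTrack` objects.
#' @param meta Data frame, one row per track, with columns `time`
#'   (minutes within phase) and `phase` (`"block"` or `"washout"`).
#' @param genes Gene panel data frame.
#' @param condition Condition label recorded in outputs.
#' @param wave_quantile Mass quantile for the emerging-wave front
#'   (default 0.9).
#' @param pd_interval Washout interval (min) over which the promoter
#'   percent decrease is computed, from the first washout sample (default
#'   20); falls back to the last washout sample if absent.
#' @param rate_genes Optional subset of gene ids used for the rate fit
#'   (e.g. genes long enough not to saturate at the TTS); default all.
#' @return A `pol2wave_analysis` list with elements `condition`,
#'   `ratios`, `block_series`, `washout_series`, `recycling`,
#'   `percent_decrease`, `pd_times`, `rate`, `fronts`, `n_genes`.
#' @export
analyze_timecourse <- function(tracks, meta, genes, condition = "condition",
                               wave_quantile = 0.9, pd_interval = 20,
                               rate_genes = NULL) {
  stopifnot(length(tracks) == nrow(meta),
            all(c("time", "phase") %in% names(meta)))
  if (!all(meta$phase %in% c("block", "washout")))
    stop("meta$phase must be 'block' or 'washout'")
  meta$condition <- condition
  ratios <- ratio_table(tracks, genes, meta[, c("time", "condition")])
  ratios$phase <- rep(meta$phase, each = nrow(genes))

  is_block <- meta$phase == "block"
  block_series <- washout_series <- NULL
  recycling <- NULL
  pd <- NA_real_
  pd_times <- c(NA_real_, NA_real_)
  rate <- NULL
  fronts <- NULL

  if (sum(is_block) >= 2L) {
    block_series <- promoter_series(tracks[is_block], genes,
                                    times = meta$time[is_block])
    bl <- body_baseline(tracks[is_block][[which.min(meta$time[is_block])]],
                        genes)
    if (is.finite(bl) && bl > 0)
      recycling <- recycling_index(block_series, bl)
  }
  if (sum(!is_block) >= 2L) {
    wt <- meta$time[!is_block]
    washout_series <- promoter_series(tracks[!is_block], genes, times = wt)
    t0 <- min(wt)
    t1 <- if ((t0 + pd_interval) %in% wt) t0 + pd_interval else max(wt)
    pd_times <- c(t0, t1)
    pd <- percent_decrease(washout_series, t0, t1)

    rg <- if (is.null(rate_genes)) genes
          else genes[genes$id %in% rate_genes, , drop = FALSE]
    wt_pos <- wt[wt > 0]
    if (length(wt_pos) >= 2L && nrow(rg) > 0L) {
      wtracks <- tracks[!is_block][wt > 0]
      med <- vapply(wtracks, function(tr)
        stats::median(wave_fronts(tr, rg, quantile = wave_quantile),
                      na.rm = TRUE), numeric(1))
      fronts <- data.frame(time = wt_pos, position = unname(med))
      if (sum(!is.na(fronts$position)) >= 2L)
        rate <- elongation_rate(fronts)
    }
  }
  structure(list(condition = condition, ratios = ratios,
                 block_series = block_series,
                 washout_series = washout_series,
                 recycling = recycling, percent_decrease = pd,
                 pd_times = pd_times, rate = rate, fronts = fronts,
                 n_genes = nrow(genes)),
            class = "pol2wave_analysis")
}

#' @export
print.pol2wave_analysis <- function(x, ...) {
  cat("pol2wave analysis for condition '", x$condition, "' (",
      x$n_genes, " genes)\n", sep = "")
  if (!is.null(x$recycling))
    cat(sprintf("  recycling index: %.4g /min\n", x$recycling$index))
  if (!is.na(x$percent_decrease))
    cat(sprintf("  promoter decrease over washout %g->%g min: %.1f%%\n",
                x$pd_times[1], x$pd_times[2], x$percent_decrease))
  if (!is.null(x$rate))
    cat(sprintf("  emerging-wave rate: %.0f bp/min\n", x$rate$rate))
  invisible(x)
}

#' Compare two conditions and flag a recycling defect
#'
#' Tabulates per-condition pausing-ratio medians per time point, washout
#' promoter percent decrease, recycling indices, elongation rates and
#' rank-test p-values, and flags a "recycling defect" when the depleted
#' condition shows both a lower recycling index and a lower washout
#' percent decrease than the control.  The index comparison carries a
#' relative margin so that replicate-to-replicate noise in matched
#' conditions cannot trigger the flag; the percent-decrease comparison
#' is directional (its absolute level is background-dominated once
#' promoters have largely emptied, so its direction corroborates the
#' index rather than gating it).
#'
#' @param control,depleted `pol2wave_analysis` objects sharing the gene
#'   panel and time points (`depleted` may be `NULL` for a
#'   single-condition report).
#' @param index_margin Relative margin on the recycling index (default
#'   0.25: the depleted index must be below the control index by more
#'   than 25\% of its magnitude).
#' @param pd_margin Absolute margin on the percent decrease, in
#'   percentage points (default 0: any decrease deficit counts).
#' @return A `condition_report` list: `summary` (per-condition,
#'   per-time-point median `pr5`/`rr3` and promoter medians), `tests`
#'   (Kruskal-Wallis p-values per washout time), `recycling_index`,
#'   `percent_decrease`, `rate`, `deltas` and `defect`.
#' @export
condition_report <- function(control, depleted = NULL, index_margin = 0.25,
                             pd_margin = 0) {
  summarize <- function(a) {
    r <- a$ratios
    agg <- do.call(rbind, lapply(split(r, list(r$phase, r$time), drop = TRUE),
      function(d) data.frame(condition = a$condition, phase = d$phase[1],
                             time = d$time[1],
                             median_pr5 = stats::median(d$pr5, na.rm = TRUE),
                             median_rr3 = stats::median(d$rr3, na.rm = TRUE),
                             median_d5 = stats::median(d$d5, na.rm = TRUE),
                             n_valid = sum(d$valid))))
    agg[order(agg$phase, agg$time), ]
  }
  summary <- summarize(control)
  tests <- NULL
  deltas <- NULL
  defect <- FALSE
  if (!is.null(depleted)) {
    if (!identical(sort(control$ratios$gene[control$ratios$time ==
                                            control$ratios$time[1]]),
                   sort(depleted$ratios$gene[depleted$ratios$time ==
                                             depleted$ratios$time[1]])))
      stop("conditions do not share the same gene panel")
    summary <- rbind(summary, summarize(depleted))
    if (!is.null(control$washout_series) &&
        !is.null(depleted$washout_series)) {
      shared <- intersect(control$washout_series$times,
                          depleted$washout_series$times)
      tests <- do.call(rbind, lapply(shared, function(tt) {
        ct <- compare_distributions(control$washout_series,
                                    depleted$washout_series, tt)
        data.frame(time = tt, statistic = ct$statistic,
                   p_value = ct$p_value)
      }))
    }
    ic <- if (!is.null(control$recycling)) control$recycling$index else NA
    id <- if (!is.null(depleted$recycling)) depleted$recycling$index else NA
    pc <- control$percent_decrease
    pd <- depleted$percent_decrease
    deltas <- data.frame(metric = c("recycling_index", "percent_decrease"),
                         control = c(ic, pc), depleted = c(id, pd),
                         delta = c(id - ic, pd - pc))
    defect <- isTRUE(!is.na(ic) && !is.na(id) && !is.na(pc) && !is.na(pd) &&
                     id < ic - index_margin * abs(ic) &&
                     pd < pc - pd_margin)
  }
  rownames(summary) <- NULL
  structure(list(summary = summary, tests = tests,
                 recycling_index = list(
                   control = control$recycling,
                   depleted = if (!is.null(depleted)) depleted$recycling),
                 percent_decrease = list(
                   control = control$percent_decrease,
                   depleted = if (!is.null(depleted))
                     depleted$percent_decrease else NULL),
                 rate = list(control = control$rate,
                             depleted = if (!is.null(depleted)) depleted$rate),
                 deltas = deltas, defect = defect,
                 margins = c(index = index_margin, pd = pd_margin)),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat("Condition report\n")
  print(x$summary, digits = 3)
  if (!is.null(x$deltas)) {
    cat("\nControl vs depleted:\n")
    print(x$deltas, digits = 3)
    cat("\nRecycling defect flagged:", x$defect, "\n")
  }
  invisible(x)
}
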