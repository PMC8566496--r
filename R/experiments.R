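# Reproducible simulation studies: parameter recovery and condition
# discrimination on synthetic data.  These functions run the full
# pipeline (simulate -> reads -> tracks -> statistics) end to end and are
# what the package's validation suite and the acceptance script execute.

#' Emerging-wave elongation-rate recovery
#'
#' For each seed, simulates a panel of long genes through a release block
#' with no pre-block transcription (the block builds a paused cohort on
#' otherwise empty templates), releases it, samples reads at several
#' washout times, rebuilds coverage tracks through the standard
#' extension/normalisation path, and regresses the per-time median
#' emerging-wave front against time.  The fitted slope estimates the true
#' elongation velocity.
#'
#' Long genes (about 200 kb) are used so that the front never saturates
#' at the TTS within the sampled interval even at 4000 bp/min.
#'
#' @param v True elongation velocity, bp/min.
#' @param seeds Integer vector of seeds; one run per seed.
#' @param n_genes Panel size (default 200).
#' @param gene_length Length range in bp (default 180-220 kb).
#' @param depth Reads per time point (default 1e6).
#' @param washout_samples Washout sample offsets in min (default
#'   `c(10, 20, 40)`).
#' @param quantile Front mass quantile (default 0.9, the leading edge).
#' @param bin_width Track bin width (default 10).
#' @param ... Further overrides passed to [sim_config()].
#' @return Data frame with columns `v_true`, `seed`, `rate`.
#' @export
rate_recovery_experiment <- function(v, seeds = 1:5, n_genes = 200L,
                                     gene_length = c(180000L, 220000L),
                                     depth = 1e6,
                                     washout_samples = c(10, 20, 40),
                                     quantile = 0.9, bin_width = 10L,
                                     ...) {
  sched <- drug_schedule(block_start = 0, block_end = 60,
                         block_samples = numeric(0),
                         washout_samples = washout_samples,
                         burn_in = 0)
  rates <- vapply(seeds, function(s) {
    cfg <- sim_config(n_genes = n_genes, gene_length = gene_length,
                      v = v, depth = depth, seed = s, ...)
    sim <- simulate_timecourse(cfg, sched)
    med <- vapply(sim$samples, function(smp) {
      tr <- make_track(smp$reads, sim$genome, bin_width = bin_width)
      stats::median(wave_fronts(tr, sim$genes, quantile = quantile),
                    na.rm = TRUE)
    }, numeric(1))
    fit <- elongation_rate(data.frame(
      time = vapply(sim$samples, `[[`, numeric(1), "phase_time"),
      position = med))
    fit$rate
  }, numeric(1))
  data.frame(v_true = v, seed = seeds, rate = rates)
}

#' Recycling-index response to the recycling probability
#'
#' For each (rho, seed) pair, simulates a block-phase time course at the
#' default condition, rebuilds tracks, and computes the promoter
#' re-accumulation index.  The index should increase with the recycling
#' probability and be at most zero when recycling is disabled.
#'
#' @param rhos Recycling probabilities to scan (default
#'   `c(0, 0.3, 0.6, 0.9)`).
#' @param seeds Seeds, one replicate per seed (default 1:5).
#' @param block_samples Block sample offsets in min (default
#'   `c(0, 10, 20, 40)`).
#' @param ... Overrides passed to [sim_config()].
#' @return Data frame with columns `rho`, `seed`, `index`.
#' @export
recycling_experiment <- function(rhos = c(0, 0.3, 0.6, 0.9), seeds = 1:5,
                                 block_samples = c(0, 10, 20, 40), ...) {
  sched <- drug_schedule(block_samples = block_samples,
                         washout_samples = numeric(0))
  grid <- expand.grid(rho = rhos, seed = seeds)
  grid$index <- mapply(function(rho, seed) {
    cfg <- sim_config(rho = rho, seed = seed, ...)
    sim <- simulate_timecourse(cfg, sched)
    tm <- tracks_from_sim(sim)
    series <- promoter_series(tm$tracks, sim$genes, times = tm$meta$time)
    base <- body_baseline(tm$tracks[[which.min(tm$meta$time)]], sim$genes)
    recycling_index(series, base)$index
  }, grid$rho, grid$seed)
  grid
}

#' One paired control/depleted pipeline run
#'
#' Simulates two conditions over a shared gene panel and schedule, runs
#' the full analysis on each, and returns the two-condition report.  With
#' `depleted_rho`/`depleted_v` equal to the control values this is a
#' null (no-effect) replicate pair.
#'
#' @param seed Master seed; the second condition uses `seed + 10000`.
#' @param depleted_rho,depleted_v Parameters of the second condition
#'   (defaults 0.2 and 1200; pass the control values for a null run).
#' @param schedule A `drug_schedule` (default [drug_schedule()]).
#' @param ... Overrides passed to both [sim_config()] calls.
#' @return A `condition_report`.
#' @export
discrimination_run <- function(seed, depleted_rho = 0.2,
                               depleted_v = 1200,
                               schedule = drug_schedule(), ...) {
  ctrl_cfg <- sim_config(seed = seed, ...)
  depl_cfg <- sim_config(rho = depleted_rho, v = depleted_v,
                         seed = seed + 10000L, ...)
  panel <- sim_gene_panel(ctrl_cfg)
  analyses <- lapply(list(control = ctrl_cfg, depleted = depl_cfg),
                     function(cfg) {
    sim <- simulate_timecourse(cfg, schedule, genes = panel$genes,
                               genome = panel$genome)
    tm <- tracks_from_sim(sim)
    analyze_timecourse(tm$tracks, tm$meta, sim$genes)
  })
  analyses$control$condition <- "control"
  analyses$control$ratios$condition <- "control"
  analyses$depleted$condition <- "depleted"
  analyses$depleted$ratios$condition <- "depleted"
  condition_report(analyses$control, analyses$depleted)
}

#' Recycling-defect discrimination study
#'
#' Runs [discrimination_run()] over several seeds for an effect
#' configuration (reduced recycling probability and velocity) and,
#' optionally, for matched null pairs, returning per-seed defect flags
#' and summary metrics.
#'
#' @param seeds Seeds (default 1:10).
#' @param null Run identical-parameter pairs instead of the effect pair
#'   (default `FALSE`).
#' @param keep_reports Attach the full per-seed `condition_report`
#'   objects as the `"reports"` attribute (default `FALSE`).
#' @param ... Overrides passed to [discrimination_run()].
#' @return Data frame with columns `seed`, `defect`,
#'   `index_control`, `index_depleted`, `pd_control`, `pd_depleted`.
#' @export
discrimination_experiment <- function(seeds = 1:10, null = FALSE,
                                      keep_reports = FALSE, ...) {
  reports <- lapply(seeds, function(s) {
    if (null)
      discrimination_run(s, depleted_rho = sim_config()$rho,
                         depleted_v = sim_config()$v, ...)
    else discrimination_run(s, ...)
  })
  rows <- lapply(seq_along(seeds), function(i) {
    rep <- reports[[i]]
    data.frame(seed = seeds[i], defect = rep$defect,
               index_control = rep$deltas$control[1],
               index_depleted = rep$deltas$depleted[1],
               pd_control = rep$deltas$control[2],
               pd_depleted = rep$deltas$depleted[2])
  })
  out <- do.call(rbind, rows)
  if (keep_reports) attr(out, "reports") <- reports
  out
}

#' Block/washout pattern summary for one condition pair
#'
#' Convenience extraction of the qualitative block/washout patterns from
#' a [discrimination_run()] report: per-condition median promoter
#' densities over block time and the washout percent decreases.
#'
#' @param report A `condition_report`.
#' @return List with `block_medians` (data frame condition x time) and
#'   `percent_decrease` (named numeric).
#' @export
block_washout_patterns <- function(report) {
  s <- report$summary
  blk <- s[s$phase == "block", c("condition", "time", "median_d5")]
  list(block_medians = blk,
       percent_decrease = c(
         control = report$percent_decrease$control,
         depleted = if (!is.null(report$percent_decrease$depleted))
           report$percent_decrease$depleted else NA_real_))
}
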