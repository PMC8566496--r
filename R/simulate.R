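# Stochastic kinetic simulator of Pol II initiation, pause release,
# elongation, termination and promoter recycling under a CDK9-inhibitor
# block/washout schedule.
#
# Kinetic scheme per gene (fixed-step tau-leaping, step dt minutes):
#   U  promoter-engaged, not yet released; Ser2-UNphosphorylated, so
#      invisible to the tracked epitope.  Created at rate k_init.
#   E  elongating at position x bp; visible.  U and R enter E at rate
#      k_release unless the drug block is engaged (then release is 0).
#      Advances by Normal(v*dt, v_sd*sqrt(dt)) truncated at 0 per step.
#   T  terminating dwell of term_dwell minutes at the TTS; visible.
#   R  promoter-engaged after recycling; visible (Ser2 retained).
#      A terminating molecule becomes R with probability rho, otherwise
#      leaves the template.
# The block suppresses pause release (and hence new visibility) but never
# touches molecules already elongating or terminating, matching the
# mechanism of CDK9 inhibition.

#' Simulator configuration
#'
#' Bundles the kinetic parameters, gene-panel size and read-sampling
#' parameters of one simulated condition.  Defaults are plausible
#' mammalian-scale values (initiation 0.5/min/gene, pause release 2/min,
#' elongation 2000 bp/min) with a gene-length range wide enough that long
#' genes retain body signal through a 40-min block, as human gene panels
#' do.
#'
#' @param n_genes Number of genes (default 50).
#' @param gene_length Length range in bp genes are drawn from uniformly
#'   (default 10000 to 200000), or a vector of `n_genes` exact lengths.
#' @param k_init Initiation rate, events/min/gene (default 0.5).
#' @param k_release Pause-release rate per promoter-engaged molecule,
#'   1/min (default 2).
#' @param v Elongation velocity, bp/min (default 2000).
#' @param v_sd Velocity jitter: per step the advance is
#'   `Normal(v*dt, v_sd*sqrt(dt))` truncated at 0 (default 200).
#' @param term_dwell Dwell time at the TTS before termination, min
#'   (default 1).
#' @param rho Recycling probability per termination, in [0, 1]
#'   (default 0.9).
#' @param depth Reads sampled per time point (default 2e5).
#' @param read_length Read length in bp (default 36).
#' @param dt Integration step in min (default 0.05); per-event
#'   probabilities `k_init*dt` and `k_release*dt` must not exceed 0.2.
#' @param background Fraction of reads drawn uniformly over each gene
#'   +/- 2 kb, emulating nonspecific ChIP signal (default 0.05).
#' @param occupancy_bin Bin width in bp of the occupancy histograms
#'   (default 50).
#' @param seed Master seed for all randomness of a run (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, gene_length = c(10000L, 200000L),
                       k_init = 0.5, k_release = 2, v = 2000, v_sd = 200,
                       term_dwell = 1, rho = 0.9, depth = 2e5,
                       read_length = 36L, dt = 0.05, background = 0.05,
                       occupancy_bin = 50L, seed = 1L) {
  stopifnot(n_genes >= 1, all(gene_length > 0),
            k_init >= 0, k_release >= 0, v >= 0, v_sd >= 0,
            term_dwell >= 0, rho >= 0, rho <= 1, depth > 0,
            read_length >= 1, dt > 0, background >= 0, background <= 1,
            occupancy_bin >= 1)
  cfg <- list(n_genes = as.integer(n_genes), gene_length = gene_length,
              k_init = k_init, k_release = k_release, v = v, v_sd = v_sd,
              term_dwell = term_dwell, rho = rho, depth = depth,
              read_length = as.integer(read_length), dt = dt,
              background = background,
              occupancy_bin = as.integer(occupancy_bin),
              seed = as.integer(seed))
  .check_dt(cfg, dt)
  structure(cfg, class = "sim_config")
}

.check_dt <- function(cfg, dt) {
  if (max(cfg$k_init * dt, cfg$k_release * dt) > 0.2)
    stop("per-step event probability exceeds 0.2; use a smaller dt ",
         "(dt <= ", format(0.2 / max(cfg$k_init, cfg$k_release)), " min)")
  invisible(TRUE)
}

#' Drug block/washout schedule
#'
#' Encodes the inhibitor schedule and the sampling design: samples taken
#' at `block_start + block_samples` minutes while release is blocked and
#' at `block_end + washout_samples` after washout.  The default mirrors a
#' 0/10/20/40-min design in both phases with a 60-min block and a 60-min
#' pre-schedule burn-in.
#'
#' @param block_start,block_end Block interval in min
#'   (`block_start < block_end`).
#' @param block_samples,washout_samples Sample offsets (min) within each
#'   phase.
#' @param burn_in Minutes simulated before `block_start` to approach
#'   steady-state occupancy (default 60).
#' @return A `drug_schedule` list with absolute `sample_times`, `phase`
#'   labels and `phase_time` offsets.
#' @export
drug_schedule <- function(block_start = 0, block_end = 60,
                          block_samples = c(0, 10, 20, 40),
                          washout_samples = c(0, 10, 20, 40),
                          burn_in = 60) {
  stopifnot(block_start < block_end, burn_in >= 0)
  block_samples <- sort(unique(block_samples))
  washout_samples <- sort(unique(washout_samples))
  if (length(block_samples) &&
      any(block_start + block_samples > block_end))
    stop("block samples extend past block_end")
  times <- c(block_start + block_samples, block_end + washout_samples)
  phase <- c(rep("block", length(block_samples)),
             rep("washout", length(washout_samples)))
  o <- order(times)
  structure(list(block_start = block_start, block_end = block_end,
                 burn_in = burn_in,
                 sample_times = times[o], phase = phase[o],
                 phase_time = c(block_samples, washout_samples)[o]),
            class = "drug_schedule")
}

#' Synthetic gene panel and genome for a simulation
#'
#' Lays `n_genes` genes with lengths drawn from the configured range on a
#' single synthetic chromosome, separated by 5-kb gaps with 3-kb
#' chromosome-end flanks, on alternating strands.  Deterministic given
#' the configuration seed.
#'
#' @param config A `sim_config`.
#' @return List with `genes` (gene panel data frame) and `genome` (named
#'   length vector).
#' @export
sim_gene_panel <- function(config) {
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$n_genes
  gl <- config$gene_length
  lens <- if (length(gl) == n && n > 2L) round(gl)
          else round(runif(n, min(gl), max(gl)))
  gap <- 5000L
  flank <- 3000L
  starts <- flank + cumsum(c(0, head(lens, -1) + gap))
  genes <- gene_panel(data.frame(
    id = sprintf("g%04d", seq_len(n)),
    chrom = "chrS",
    strand = rep_len(c("+", "-"), n),
    start = starts, end = starts + lens))
  genome <- genome_table(c(chrS = max(genes$end) + flank))
  list(genes = genes, genome = genome)
}

# Fresh empty simulator state for a gene panel.
sim_init_state <- function(genes) {
  n <- nrow(genes)
  list(U = integer(n), R = integer(n),
       E_gene = integer(0), E_pos = numeric(0),
       T_gene = integer(0), T_left = numeric(0),
       gene_length = genes$length)
}

#' Advance the simulator state by one tau-leap step
#'
#' One fixed step of the kinetic scheme: optional pause release (U and R
#' enter elongation unless `in_block`), truncated-normal advance of
#' elongating molecules, entry into the termination dwell at the gene
#' end, recycling or loss at dwell expiry, and new (invisible) initiation
#' events.
#'
#' @param state Simulator state (see [sim_init_state] internals): counts
#'   `U`, `R` per gene, elongating molecules (`E_gene`, `E_pos`),
#'   terminating molecules (`T_gene`, `T_left`), and `gene_length`.
#' @param config A `sim_config`.
#' @param in_block Logical: is the release block engaged during this
#'   step?
#' @param dt Step size in min (default `config$dt`); per-event
#'   probabilities above 0.2 are an error instructing a smaller dt.
#' @return The advanced state.
#' @export
sim_step <- function(state, config, in_block, dt = config$dt) {
  .check_dt(config, dt)
  n <- length(state$U)
  L <- state$gene_length
  if (!in_block && config$k_release > 0) {
    p_rel <- config$k_release * dt
    relU <- rbinom(n, state$U, p_rel)
    relR <- rbinom(n, state$R, p_rel)
    state$U <- state$U - relU
    state$R <- state$R - relR
    nw <- relU + relR
    if (sum(nw) > 0) {
      g <- rep.int(seq_len(n), nw)
      state$E_gene <- c(state$E_gene, g)
      state$E_pos <- c(state$E_pos, numeric(length(g)))
    }
  }
  m <- length(state$E_pos)
  if (m > 0) {
    adv <- rnorm(m, config$v * dt, config$v_sd * sqrt(dt))
    adv[adv < 0] <- 0
    state$E_pos <- state$E_pos + adv
    done <- state$E_pos >= L[state$E_gene]
    if (any(done)) {
      state$T_gene <- c(state$T_gene, state$E_gene[done])
      state$T_left <- c(state$T_left,
                        rep(config$term_dwell, sum(done)))
      state$E_gene <- state$E_gene[!done]
      state$E_pos <- state$E_pos[!done]
    }
  }
  if (length(state$T_left) > 0) {
    state$T_left <- state$T_left - dt
    out <- state$T_left <= 0
    if (any(out)) {
      g <- state$T_gene[out]
      rec <- runif(length(g)) < config$rho
      if (any(rec))
        state$R <- state$R + tabulate(g[rec], nbins = n)
      state$T_gene <- state$T_gene[!out]
      state$T_left <- state$T_left[!out]
    }
  }
  if (config$k_init > 0)
    state$U <- state$U + rbinom(n, 1L, config$k_init * dt)
  state
}

# Total molecules currently on templates (all compartments).
sim_total_molecules <- function(state) {
  sum(state$U) + sum(state$R) + length(state$E_pos) + length(state$T_gene)
}

#' Ser2-visible occupancy histograms
#'
#' Counts of Ser2-visible molecules per position bin, in transcription
#' coordinates per gene.  Elongating molecules contribute at their
#' position, recycled promoter-engaged molecules at the TSS, terminating
#' molecules at the TTS; unreleased (unphosphorylated) molecules
#' contribute nothing.
#'
#' @param state Simulator state.
#' @param bin_width Bin width in bp (default 50).
#' @return List of integer vectors (one per gene, length
#'   `ceiling(length / bin_width)`), with attribute `bin_width`.
#' @export
visible_occupancy <- function(state, bin_width = 50L) {
  n <- length(state$U)
  L <- state$gene_length
  nb <- as.integer(ceiling(L / bin_width))
  g <- c(state$E_gene, rep.int(seq_len(n), state$R), state$T_gene)
  p <- c(pmin(state$E_pos, L[state$E_gene] - 1),
         rep.int(0, sum(state$R)),
         L[state$T_gene] - 1)
  b <- pmin(as.integer(p %/% bin_width) + 1L, nb[pmax(g, 1L)])
  bs <- split(b, factor(g, levels = seq_len(n)))
  occ <- lapply(seq_len(n), function(i) tabulate(bs[[i]], nbins = nb[i]))
  attr(occ, "bin_width") <- as.integer(bin_width)
  occ
}

#' Sample sequencing reads from an occupancy snapshot
#'
#' Draws read 5' positions multinomially with weights proportional to the
#' visible occupancy, plus a uniform background fraction over each gene
#' +/- 2 kb, places them on the gene's strand with the configured read
#' length, and returns exactly `depth` reads.
#'
#' @param occ Occupancy histograms from [visible_occupancy()].
#' @param genes Gene panel data frame the occupancy refers to.
#' @param genome Genome table.
#' @param depth Number of reads to draw.
#' @param read_length Read length in bp.
#' @param background Uniform background fraction (default 0.05).
#' @return `GRanges` of reads (with seqinfo), suitable for
#'   [write_bed()] or [make_track()].
#' @export
sample_reads <- function(occ, genes, genome, depth, read_length = 36L,
                         background = 0.05) {
  genome <- genome_table(genome)
  bw <- attr(occ, "bin_width")
  counts <- unlist(occ, use.names = FALSE)
  total_sig <- sum(counts)
  if (total_sig == 0 && background == 0)
    stop("zero total occupancy and zero background: nothing to sample")
  depth <- as.integer(round(depth))
  n_bg <- if (total_sig == 0) depth else rbinom(1L, depth, background)
  n_sig <- depth - n_bg

  gene_of_bin <- rep.int(seq_len(nrow(genes)), lengths(occ))
  first_bin <- cumsum(c(0L, head(lengths(occ), -1L)))
  tx_all <- numeric(0)
  g_all <- integer(0)
  if (n_sig > 0) {
    draws <- as.integer(rmultinom(1L, n_sig, prob = counts))
    nz <- which(draws > 0L)
    bins <- rep.int(nz, draws[nz])
    g_sig <- gene_of_bin[bins]
    bin_in_gene <- bins - first_bin[g_sig] - 1L   # 0-based bin index
    off0 <- bin_in_gene * bw
    w <- pmin(bw, genes$length[g_sig] - off0)
    tx <- off0 + floor(runif(length(bins)) * w)
    g_all <- c(g_all, g_sig)
    tx_all <- c(tx_all, tx)
  }
  if (n_bg > 0) {
    bg_margin <- 2000
    wts <- genes$length + 2 * bg_margin
    draws <- as.integer(rmultinom(1L, n_bg, prob = wts))
    nz <- which(draws > 0L)
    g_bg <- rep.int(nz, draws[nz])
    tx <- floor(runif(length(g_bg)) * wts[g_bg]) - bg_margin
    g_all <- c(g_all, g_bg)
    tx_all <- c(tx_all, tx)
  }
  plus <- genes$strand[g_all] == "+"
  p5 <- ifelse(plus, genes$start[g_all] + tx_all,
               genes$end[g_all] - 1 - tx_all)
  chrom <- genes$chrom[g_all]
  glen <- unname(genome[chrom])
  p5 <- pmax(pmin(p5, glen - 1), 0)
  s0 <- ifelse(plus, p5, pmax(p5 - read_length + 1, 0))   # 0-based start
  e0 <- ifelse(plus, pmin(p5 + read_length, glen), p5 + 1)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s0 + 1L, end = e0),
                         strand = ifelse(plus, "+", "-"),
                         seqinfo = .seqinfo_from_genome(genome))
}

#' Simulate one condition over a block/washout schedule
#'
#' Runs the kinetic model from an empty template through burn-in, block
#' and washout, recording a visible-occupancy snapshot and a sampled read
#' set at every scheduled sample time.  All randomness derives from
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @param schedule A `drug_schedule`.
#' @param genes,genome Optional shared gene panel (from
#'   [sim_gene_panel()]); generated from `config` when omitted.
#' @return A `sim_timecourse`: list with `samples` (per sample time:
#'   `time`, `phase`, `phase_time`, `occupancy`, `reads`,
#'   `visible_molecules`), `genes`, `genome`, `config`, `schedule`.
#' @export
simulate_timecourse <- function(config, schedule, genes = NULL,
                                genome = NULL) {
  if (is.null(genes) || is.null(genome)) {
    panel <- sim_gene_panel(config)
    genes <- panel$genes
    genome <- panel$genome
  }
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  dt <- config$dt
  t0 <- schedule$block_start - schedule$burn_in
  n_steps <- as.integer(round((max(schedule$sample_times) - t0) / dt))
  sample_steps <- as.integer(round((schedule$sample_times - t0) / dt))
  state <- sim_init_state(genes)
  samples <- vector("list", length(schedule$sample_times))
  take <- function(k) {
    i <- match(k, sample_steps)
    occ <- visible_occupancy(state, bin_width = config$occupancy_bin)
    reads <- sample_reads(occ, genes, genome, depth = config$depth,
                          read_length = config$read_length,
                          background = config$background)
    samples[[i]] <<- list(time = schedule$sample_times[i],
                          phase = schedule$phase[i],
                          phase_time = schedule$phase_time[i],
                          occupancy = occ, reads = reads,
                          visible_molecules =
                            sum(vapply(occ, sum, numeric(1))))
  }
  if (0L %in% sample_steps) take(0L)
  for (k in seq_len(n_steps)) {
    t_step <- t0 + (k - 1L) * dt   # time at the start of the step
    in_block <- t_step >= schedule$block_start &&
      t_step < schedule$block_end
    state <- sim_step(state, config, in_block = in_block, dt = dt)
    if (k %in% sample_steps) take(k)
  }
  structure(list(samples = samples, genes = genes, genome = genome,
                 config = config, schedule = schedule),
            class = "sim_timecourse")
}

#' @export
print.sim_timecourse <- function(x, ...) {
  cat("sim_timecourse:", length(x$samples), "samples,",
      nrow(x$genes), "genes, seed", x$config$seed, "\n")
  invisible(x)
}

#' Build coverage tracks from a simulated time course
#'
#' Convenience wrapper turning every sampled read set of a
#' [simulate_timecourse()] run into a depth-normalised `CoverageTrack`.
#'
#' @param sim A `sim_timecourse`.
#' @param extension Fragment extension in bp (default 300).
#' @param bin_width Track bin width (default 10).
#' @param target_depth Normalisation target depth (default 5e7).
#' @return List with `tracks` (list of `CoverageTrack`) and `meta`
#'   (data frame `time`, `phase`; `time` is minutes within phase).
#' @export
tracks_from_sim <- function(sim, extension = 300L, bin_width = 10L,
                            target_depth = 5e7) {
  tracks <- lapply(sim$samples, function(s)
    make_track(s$reads, sim$genome, extension = extension,
               bin_width = bin_width, target_depth = target_depth))
  meta <- data.frame(
    time = vapply(sim$samples, `[[`, numeric(1), "phase_time"),
    phase = vapply(sim$samples, `[[`, character(1), "phase"))
  names(tracks) <- paste0(meta$phase, "_t", meta$time)
  list(tracks = tracks, meta = meta)
}

#' Generate a two-condition synthetic dataset on disk
#'
#' Simulates every configured condition over a shared gene panel and
#' schedule and writes one BED6 read file per (condition, sample time), a
#' gene-model TSV, a chrom.sizes table, a ground-truth JSON and a run
#' manifest with content hashes.
#'
#' @param configs Named list of `sim_config` objects (e.g.
#'   `list(control = ..., depleted = ...)`); the gene panel is generated
#'   from the first.
#' @param schedule A `drug_schedule`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `files`, `truth` and the shared
#'   `genes`/`genome`.
#' @export
make_timecourse <- function(configs, schedule, outdir) {
  stopifnot(is.list(configs), length(configs) >= 1L,
            !is.null(names(configs)), all(nzchar(names(configs))))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panel <- sim_gene_panel(configs[[1]])
  files <- character(0)
  gene_path <- file.path(outdir, "genes.tsv")
  write_genes(panel$genes, gene_path)
  cs_path <- file.path(outdir, "chrom.sizes")
  utils::write.table(data.frame(names(panel$genome),
                                unname(panel$genome)),
                     cs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(files, gene_path, cs_path)
  truth <- list(schedule = unclass(schedule), conditions = list())
  for (cond in names(configs)) {
    cfg <- configs[[cond]]
    sim <- simulate_timecourse(cfg, schedule, genes = panel$genes,
                               genome = panel$genome)
    vis <- numeric(0)
    for (s in sim$samples) {
      bed <- file.path(outdir, sprintf("%s_%s_t%02d.bed", cond, s$phase,
                                       s$phase_time))
      write_bed(s$reads, bed)
      files <- c(files, bed)
      vis <- c(vis, s$visible_molecules)
    }
    truth$conditions[[cond]] <- list(
      config = unclass(cfg),
      visible_molecules = data.frame(
        time = vapply(sim$samples, `[[`, numeric(1), "time"),
        phase = vapply(sim$samples, `[[`, character(1), "phase"),
        visible = vis))
  }
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, truth_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(truth_path)),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(list(files = c(files, file.path(outdir, "manifest.json")),
                 truth = truth, genes = panel$genes,
                 genome = panel$genome))
}
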