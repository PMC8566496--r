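# Run-level entry points behind the command-line interface: dataset
# generation from a YAML configuration and end-to-end analysis of a
# dataset directory, with run manifests.

.required_sim_fields <- c("k_init", "k_release", "v", "v_sd", "term_dwell",
                          "rho", "depth")

.config_from_list <- function(lst, where) {
  missing <- setdiff(.required_sim_fields, names(lst))
  if (length(missing))
    stop("invalid configuration (", where, "): missing field(s) ",
         paste(missing, collapse = ", "))
  do.call(sim_config, lst)
}

#' Generate a synthetic dataset from a YAML configuration
#'
#' Reads a single-file YAML configuration with sections `control`,
#' optionally `depleted` (simulator parameters; see [sim_config()]) and
#' `schedule` (see [drug_schedule()]), and writes the dataset with
#' [make_timecourse()].  Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config_path Path to the YAML file.
#' @param outdir Output directory.
#' @return Invisibly, the [make_timecourse()] result.
#' @export
run_simulate <- function(config_path, outdir) {
  if (!file.exists(config_path))
    stop("configuration file not found: ", config_path)
  y <- yaml::read_yaml(config_path)
  if (is.null(y$control)) stop("invalid configuration: missing 'control'")
  configs <- list(control = .config_from_list(y$control, "control"))
  if (!is.null(y$depleted))
    configs$depleted <- .config_from_list(y$depleted, "depleted")
  sched <- if (is.null(y$schedule)) drug_schedule()
           else do.call(drug_schedule, y$schedule)
  message("simulating ", length(configs), " condition(s) into ", outdir)
  make_timecourse(configs, sched, outdir)
}

# Parse "<condition>_<phase>_t<MM>.bed" names written by make_timecourse.
.parse_bed_names <- function(beds) {
  m <- regmatches(basename(beds),
                  regexec("^(.+)_(block|washout)_t([0-9]+)\\.bed$",
                          basename(beds)))
  ok <- lengths(m) == 4L
  if (!all(ok))
    stop("unrecognised BED file name(s): ",
         paste(basename(beds)[!ok], collapse = ", "))
  data.frame(path = beds,
             condition = vapply(m, `[[`, character(1), 2L),
             phase = vapply(m, `[[`, character(1), 3L),
             time = as.numeric(vapply(m, `[[`, character(1), 4L)))
}

#' Analyse a timed block/washout dataset directory
#'
#' Discovers per-(condition, phase, time) BED read files plus `genes.tsv`
#' and `chrom.sizes` in a dataset directory (the layout written by
#' [make_timecourse()]), builds depth-normalised tracks, runs the pausing,
#' metagene and dynamics statistics per condition, compares the first two
#' conditions when both are present, and writes tables, a JSON report,
#' summary plots and a manifest into `outdir`.
#'
#' @param dataset_dir Dataset directory.
#' @param outdir Output directory (created if needed).
#' @param extension Fragment extension in bp (default 300).
#' @param target_depth Normalisation target depth (default 5e7).
#' @param bin_width Track bin width (default 10).
#' @param body_bins,flank Metagene parameters (defaults 100 and 2000).
#' @param wave_quantile Emerging-wave quantile (default 0.9).
#' @param plots Write summary plots as PDF (default `TRUE`).
#' @return Invisibly, a list with the per-condition analyses and the
#'   `condition_report` (or `NULL` for a single condition).
#' @export
run_analyze <- function(dataset_dir, outdir, extension = 300L,
                        target_depth = 5e7, bin_width = 10L,
                        body_bins = 100L, flank = 2000L,
                        wave_quantile = 0.9, plots = TRUE) {
  genes_path <- file.path(dataset_dir, "genes.tsv")
  cs_path <- file.path(dataset_dir, "chrom.sizes")
  for (p in c(genes_path, cs_path))
    if (!file.exists(p)) stop("dataset file missing: ", p)
  genome <- read_chrom_sizes(cs_path)
  genes <- load_genes(genes_path, genome = genome)
  if (nrow(genes) == 0) stop("empty gene panel after filtering")
  beds <- list.files(dataset_dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(beds)) stop("no BED read files in ", dataset_dir)
  man <- .parse_bed_names(beds)
  conds <- unique(man$condition)
  times_by_cond <- lapply(conds, function(cc)
    paste(man$phase, man$time)[man$condition == cc])
  if (length(conds) > 1L &&
      !all(vapply(times_by_cond, identical, logical(1),
                  y = times_by_cond[[1]]))) {
    all_t <- unique(unlist(times_by_cond))
    miss <- lapply(times_by_cond, function(x) setdiff(all_t, x))
    stop("conditions have mismatched sample times; missing: ",
         paste(unlist(miss), collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  analyses <- list()
  profiles <- list()
  for (cc in conds) {
    sel <- man[man$condition == cc, , drop = FALSE]
    sel <- sel[order(sel$phase, sel$time), , drop = FALSE]
    message("building ", nrow(sel), " track(s) for condition '", cc, "'")
    tracks <- lapply(sel$path, function(p)
      make_track(read_bed(p, genome), genome, extension = extension,
                 bin_width = bin_width, target_depth = target_depth))
    meta <- sel[, c("time", "phase")]
    analyses[[cc]] <- analyze_timecourse(tracks, meta, genes,
                                         condition = cc,
                                         wave_quantile = wave_quantile)
    profiles[[cc]] <- lapply(seq_along(tracks), function(k)
      scaled_metagene(tracks[[k]], genes, body_bins = body_bins,
                      flank = flank))
    names(profiles[[cc]]) <- paste0(meta$phase, "_t", meta$time)
  }

  report <- if (length(conds) >= 2L)
    condition_report(analyses[[1]], analyses[[2]]) else
    condition_report(analyses[[1]])

  # tables
  ratios <- do.call(rbind, lapply(analyses, `[[`, "ratios"))
  utils::write.table(ratios, file.path(outdir, "ratio_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof_tab <- do.call(rbind, lapply(names(profiles), function(cc)
    do.call(rbind, lapply(names(profiles[[cc]]), function(nm) {
      d <- as.data.frame(profiles[[cc]][[nm]])
      d$condition <- cc
      d$sample <- nm
      d
    }))))
  utils::write.table(prof_tab, file.path(outdir, "metagene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report_json <- list(
    conditions = conds,
    n_genes = nrow(genes),
    defect = report$defect,
    deltas = report$deltas,
    tests = report$tests,
    percent_decrease = report$percent_decrease,
    recycling_index = lapply(report$recycling_index, function(r)
      if (!is.null(r)) unclass(r)),
    elongation_rate = lapply(report$rate, function(r)
      if (!is.null(r)) unclass(r)),
    note = paste("recycling_index is a package-defined promoter",
                 "re-accumulation summary"))
  jsonlite::write_json(report_json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  if (plots) {
    grDevices::pdf(file.path(outdir, "plots.pdf"), width = 7, height = 5)
    for (cc in conds) {
      for (nm in names(profiles[[cc]]))
        plot(profiles[[cc]][[nm]], main = paste(cc, nm))
      plot_sorted_ratios(analyses[[cc]]$ratios,
                         main = paste("sorted 5' pausing ratios:", cc))
    }
    grDevices::dev.off()
  }
  outs <- list.files(outdir, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest <- list(files = data.frame(file = basename(outs),
                                      md5 = unname(tools::md5sum(outs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(list(analyses = analyses, report = report))
}
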