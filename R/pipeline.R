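#' Read and validate a pipeline run configuration
#'
#' YAML keys (see the demo config shipped at
#' `system.file("extdata", "demo_config.yaml", package = "fusion4c")`):
#' resolutions (`fine`, `coarse`, `report`), detection thresholds
#' (`z_threshold`, `min_effect`, `exclusion_flank`, `tolerance`, `min_size`,
#' `min_callers`), a `seed`, and either a `simulate:` block (cohort
#' parameters for [simulate_cohort()]) or a `samples:` sheet of matrix paths
#' plus an `anchors:` YAML path. Validation happens before any compute: the
#' coarse resolution must be divisible by the fine one, the report
#' resolution by the coarse one, and referenced paths must exist.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(fine = 1e4, coarse = 5e4, report = 5e5,
                   z_threshold = 4, min_effect = 0.15, exclusion_flank = 1e6,
                   tolerance = 1000, min_size = 10000, min_callers = 2,
                   seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  for (k in c("fine", "coarse", "report", "z_threshold", "min_effect",
              "exclusion_flank", "tolerance", "min_size", "min_callers", "seed"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$simulate))
    cfg$simulate <- lapply(cfg$simulate, function(v) {
      # YAML may hand back numbers as strings (e.g. "3.0e6"); coerce scalars
      nv <- suppressWarnings(as.numeric(v))
      if (length(v) == 1L && !is.na(nv) && !is.logical(v)) nv else v
    })
  if (cfg$coarse %% cfg$fine != 0)
    stop_fmt("coarse resolution (%s) must be divisible by fine (%s)",
             cfg$coarse, cfg$fine)
  if (cfg$report %% cfg$coarse != 0)
    stop_fmt("report resolution (%s) must be divisible by coarse (%s)",
             cfg$report, cfg$coarse)
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$samples) || is.null(cfg$anchors))
      stop_fmt("config needs either a 'simulate' block or 'samples' + 'anchors'")
    paths <- c(vapply(cfg$samples, function(s) s$matrix, ""), cfg$anchors)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L)
      stop_fmt("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load) contact
#' matrices, balance, compartment scoring and cross-sample comparison,
#' virtual 4C profiling with exclusive-peak detection, SV consensus on
#' simulated call sets with matched-normal subtraction — and writes a
#' structured report. Every output carries the configuration hash and seed;
#' rerunning with the same configuration and seed reproduces the report
#' byte-identically.
#'
#' @param config A [read_run_config()] result, a YAML path, or a list.
#' @param outdir Output directory (created if needed).
#' @return The run report (a list), invisibly; `report.json`, per-sample
#'   matrices/profiles/tracks and consensus tables are written to `outdir`.
#'   The report's `report_md5` is the checksum of the written JSON.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(outdir, "config_used.yaml")
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(cfg_plain, cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  coarse_factor <- cfg$coarse %/% cfg$fine

  # --- stage: simulate or load -------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sim_args$bin_size <- cfg$fine
    cohort <- do.call(simulate_cohort, sim_args)
    anchors <- cohort$anchors
    mats <- lapply(cohort$samples, function(s) s$matrix)
    names(mats) <- vapply(cohort$samples, function(s) s$name, "")
    truth <- do.call(rbind, lapply(cohort$samples, function(s)
      if (nrow(s$truth) > 0L) as.data.frame(s$truth) else NULL))
    labels <- cohort$compartment_labels
    for (nm in names(mats))
      write_matrix(mats[[nm]], file.path(outdir, paste0(nm, ".coo")))
    if (!is.null(truth) && nrow(truth) > 0L)
      write_bedpe(sv_calls(truth$chrom1, truth$pos1, truth$chrom2, truth$pos2,
                           sv_type = truth$sv_type, caller = "truth",
                           sample = truth$sample, truth_id = truth$truth_id),
                  file.path(outdir, "truth_events.bedpe"))
    write_bedgraph(mats[[1L]]$bins, a_density_track(labels),
                   file.path(outdir, "compartment_truth.bedGraph"))
  } else {
    anchors <- read_anchor_yaml(cfg$anchors)
    mats <- lapply(cfg$samples, function(s) {
      m <- read_matrix(s$matrix)
      m$sample <- s$name
      m
    })
    names(mats) <- vapply(cfg$samples, function(s) s$name, "")
    truth <- NULL
    labels <- NULL
  }

  # --- stage: balance ----------------------------------------------------
  mats <- lapply(mats, function(m) set_weights(m, balance(m)))
  for (nm in names(mats))
    write_bedgraph(mats[[nm]]$bins, mats[[nm]]$weights,
                   file.path(outdir, paste0(nm, ".weights.bedGraph")))

  # --- stage: compartments ------------------------------------------------
  comp <- NULL
  similarity <- NULL
  if (!is.null(labels)) {
    chrom <- anchors$background$chrom
    bins1 <- mats[[1L]]$bins
    on_chrom <- bins1$chrom == chrom
    orientation <- a_density_track(labels)[on_chrom]
    tracks <- lapply(mats, compartment_score, chrom = chrom,
                     orientation_track = orientation)
    for (nm in names(mats))
      write_bedgraph(bins1[on_chrom, ], tracks[[nm]]$score,
                     file.path(outdir, paste0(nm, ".compartments.bedGraph")))
    similarity <- compare_tracks(tracks)
    write_similarity_tsv(similarity, file.path(outdir, "compartment_similarity.tsv"))
    if (!is.null(similarity$linkage))
      write_linkage_newick(similarity, file.path(outdir, "compartment_linkage.nwk"))
    comp <- lapply(tracks, function(t) {
      at <- compartment_at(t, anchors$background)
      list(label = at$label, mean_score = at$mean_score)
    })
  }

  # --- stage: virtual 4C --------------------------------------------------
  profiles <- lapply(mats, extract_profile, anchors = anchors,
                     coarse_factor = coarse_factor)
  for (nm in names(mats))
    write_profile_tsv(profiles[[nm]], file.path(outdir, paste0(nm, ".v4c.tsv")))
  peaks <- detect_partner_peaks(profiles,
                                exclusion_flank = cfg$exclusion_flank,
                                z_threshold = cfg$z_threshold,
                                min_effect = cfg$min_effect)
  utils::write.table(peaks, file.path(outdir, "partner_peaks.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: SV consensus (simulated call sets over the planted truth) ---
  consensus_report <- NULL
  if (!is.null(truth) && nrow(truth) > 0L) {
    callsets <- simulate_callsets(truth, n_callers = 4L, jitter_sd = 300,
                                  dropout = 0.1, fp_per_caller = 3L,
                                  chrom_lengths = attr(mats[[1L]]$bins, "chrom_lengths"),
                                  seed = cfg$seed + 101)
    consensus <- match_calls(callsets, tolerance = cfg$tolerance)
    filtered <- filter_consensus(consensus, min_size = cfg$min_size,
                                 min_callers = cfg$min_callers)
    filtered <- subtract_normal(filtered, list(), tolerance = cfg$tolerance)
    write_bedpe(sv_calls(filtered$chrom1, filtered$pos1, filtered$chrom2,
                         filtered$pos2, sv_type = filtered$sv_type,
                         caller = filtered$callers,
                         truth_id = filtered$truth_id),
                file.path(outdir, "consensus_svs.bedpe"))
    consensus_report <- lapply(seq_len(nrow(filtered)), function(i) list(
      chrom1 = filtered$chrom1[i], pos1 = filtered$pos1[i],
      chrom2 = filtered$chrom2[i], pos2 = filtered$pos2[i],
      sv_type = filtered$sv_type[i], n_callers = filtered$n_callers[i],
      somatic = filtered$somatic[i]))
  }

  # --- report -------------------------------------------------------------
  fusion_candidates <- lapply(seq_len(nrow(peaks)), function(i) list(
    sample = peaks$sample[i], locus = sprintf("%s:%d-%d", peaks$chrom[i],
                                              as.integer(peaks$start[i]),
                                              as.integer(peaks$end[i])),
    peak_z = round(peaks$peak_z[i], 3), n_bins = peaks$n_bins[i]))
  report <- list(
    config_hash = config_hash,
    seed = cfg$seed,
    samples = names(mats),
    fusion_candidates = fusion_candidates,
    fusion_sample = if (nrow(peaks) > 0L) peaks$sample[1L] else NA,
    partner_locus = if (nrow(peaks) > 0L)
      sprintf("%s:%d-%d", peaks$chrom[1L], as.integer(peaks$start[1L]),
              as.integer(peaks$end[1L])) else NA,
    compartments_at_viewpoint = comp,
    consensus_svs = consensus_report)
  report_file <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  report$report_md5 <- unname(tools::md5sum(report_file))
  invisible(report)
}
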