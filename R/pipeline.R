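#' Pipeline run configuration
#'
#' One flat configuration shared by all pipeline commands. Defaults are the
#' canonical analysis constants: variance-stabilization scale p = 500,
#' Gaussian kernel sigma = 2500 bp, QC zero-count threshold 0.75 on the 2-Mb
#' bait window, 5 masked flanking fragments per side, rhythm significance
#' alpha = 0.01, 500-bp track bins with a 7-bin running average, and Hill
#' colour constants (n = 5, k_a = 0.5, k_p = 4.5).
#'
#' @param ... Overrides of the defaults, by name.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(p = 500, sigma = 2500, qc_zero_fraction = 0.75,
              qc_window_half_width = 1e6, n_flank = 5, alpha = 0.01,
              bin_size = 500, smooth_half_width = 3,
              hill_n = 5, k_a = 0.5, k_p = 4.5, rng_seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

.write_resolved_config <- function(cfg, out_dir, extra = list()) {
  x <- c(unclass(cfg), extra)
  yaml::write_yaml(x, file.path(out_dir, "config.yaml"))
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate an experiment and write it to disk
#'
#' Runs the synthetic-data generator end to end and writes the fragment map
#' (BED4), count table (TSV), sample sheet (TSV), ground-truth tables (TSV)
#' and the resolved configuration (YAML) into \code{out_dir}.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param peaks List of \code{\link{planted_peak}} objects.
#' @param sheet A \code{\link{sample_sheet}}.
#' @param out_dir Output directory (created if needed).
#' @param cfg A \code{\link{run_config}}.
#' @param ko_fold_attenuation Passed to \code{\link{simulate_experiment}}.
#' @return Invisibly, the \code{fourc_sim} object with an added
#'   \code{files} element.
#' @export
run_simulate <- function(sim, peaks = list(), sheet, out_dir,
                         cfg = run_config(), ko_fold_attenuation = 1) {
  .ensure_dir(out_dir)
  x <- simulate_experiment(sim, peaks, sheet,
                           ko_fold_attenuation = ko_fold_attenuation)
  bait_id <- x$map$id[bait_index(x$map)]
  x$sheet$bait <- bait_id
  files <- c(map = file.path(out_dir, "fragments.bed"),
             counts = file.path(out_dir, "counts.tsv"),
             sheet = file.path(out_dir, "samples.tsv"),
             truth_expected = file.path(out_dir, "truth_expected.tsv"),
             truth_peaks = file.path(out_dir, "truth_peaks.tsv"))
  write_fragment_map(x$map, files["map"])
  write_count_table(x$counts, files["counts"])
  write_sample_sheet(x$sheet, files["sheet"])
  utils::write.table(data.frame(fragment_id = rownames(x$truth$expected),
                                x$truth$expected, check.names = FALSE),
                     files["truth_expected"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$truth$peaks, files["truth_peaks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_resolved_config(cfg, out_dir, extra = c(unclass(sim), bait = bait_id))
  x$files <- files
  invisible(x)
}

.apply_qc <- function(map, counts, cfg) {
  qc <- qc_experiment(map, counts, cfg$qc_window_half_width,
                      cfg$qc_zero_fraction)
  if (any(!qc$pass))
    warning(sprintf("dropping %d sample(s) failing QC: %s", sum(!qc$pass),
                    paste(qc$sample_id[!qc$pass], collapse = ", ")))
  list(qc = qc, keep = qc$sample_id[qc$pass])
}

#' Run the rhythm-detection pipeline on a time-course experiment
#'
#' QC filtering, bait-flank masking, normalization, variance stabilization,
#' LWMR smoothing with per-time condition effects, Fourier chi-square rhythm
#' testing, and output of browser tracks: smoothed per-time bedGraphs, a
#' per-fragment results TSV, a BED9 peak-time colour track (fragments with
#' p < alpha) and a -log10(p) bedGraph.
#'
#' @param map A \code{\link{fragment_map}} with a bait.
#' @param counts Count matrix, fragments x samples.
#' @param sheet A \code{\link{sample_sheet}} (six time points).
#' @param out_dir Output directory.
#' @param cfg A \code{\link{run_config}}.
#' @param genotype Genotype analysed for rhythms (default \code{"WT"} when
#'   present, else the single genotype in the sheet).
#' @return Invisibly, a list: \code{results} (rhythm table), \code{profile},
#'   \code{qc}, \code{files}, \code{log}.
#' @export
run_rhythm <- function(map, counts, sheet, out_dir, cfg = run_config(),
                       genotype = NULL) {
  .ensure_dir(out_dir)
  qcres <- .apply_qc(map, counts, cfg)
  sheet2 <- sheet[sheet$sample_id %in% qcres$keep, , drop = FALSE]
  class(sheet2) <- class(sheet)
  if (is.null(genotype))
    genotype <- if ("WT" %in% sheet2$genotype) "WT" else unique(sheet2$genotype)[1L]
  sheet2 <- sheet2[sheet2$genotype == genotype, , drop = FALSE]
  class(sheet2) <- c("sample_sheet", "data.frame")
  times <- sort(unique(sheet2$time))
  if (length(times) != 6L)
    stop(sprintf("rhythm analysis needs six time points after QC; %d remain",
                 length(times)))
  counts2 <- counts[, sheet2$sample_id, drop = FALSE]
  profile <- smooth_profile(counts2, map, sheet2, condition_by = "time",
                            scheme = weight_scheme(cfg$sigma), p = cfg$p,
                            n_flank = cfg$n_flank)
  res <- rhythm_analysis(profile, alpha = cfg$alpha)
  files <- c(results = file.path(out_dir, "rhythm_results.tsv"),
             colors = file.path(out_dir, "peak_time.bed"),
             neglogp = file.path(out_dir, "neglog10p.bedGraph"))
  utils::write.table(res, files["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (tm in times) {
    lev <- sprintf("ZT%02d", as.integer(tm))
    f <- file.path(out_dir, sprintf("smoothed_%s.bedGraph", lev))
    keepf <- !profile$mask
    write_bedgraph(map$chrom[keepf], map$start[keepf], map$end[keepf],
                   profile$fitted[keepf, lev], f)
    files[paste0("smoothed_", lev)] <- f
  }
  sig <- res[res$rhythmic, , drop = FALSE]
  pcol <- color_params(cfg$hill_n, cfg$k_a, cfg$k_p)
  write_color_track(sig$chrom, sig$start, sig$end,
                    color = if (nrow(sig)) phase_to_color(sig$peak_time, 1, pcol) else character(0),
                    brightness = rep(1, nrow(sig)),
                    path = files["colors"], name = sig$id)
  write_bedgraph(res$chrom, res$start, res$end, -log10(res$p), files["neglogp"])
  .write_resolved_config(cfg, out_dir,
                         extra = list(genotype = genotype,
                                      samples_dropped_qc = sum(!qcres$qc$pass),
                                      fragments_masked = sum(profile$mask),
                                      fragments_tested = sum(!is.na(res$p))))
  invisible(list(results = res, profile = profile, qc = qcres$qc,
                 files = files,
                 log = list(samples_dropped = sum(!qcres$qc$pass),
                            fragments_masked = sum(profile$mask),
                            fragments_tested = sum(!is.na(res$p)))))
}

#' Compare two conditions fragment by fragment
#'
#' Fits the smoothing model with the two requested conditions and writes the
#' per-fragment Z-score and p-value tracks plus a results TSV.
#'
#' @param map,counts,sheet As in \code{\link{run_rhythm}}.
#' @param condition_pair Character vector of two condition labels, as
#'   produced by \code{\link{sheet_conditions}} with \code{condition_by}
#'   (e.g. \code{c("ZT08", "ZT20")} or \code{c("WT", "KO")}).
#' @param out_dir Output directory.
#' @param cfg A \code{\link{run_config}}.
#' @param condition_by Grouping rule (see \code{\link{sheet_conditions}}).
#' @return Invisibly, a list: \code{results}, \code{profile}, \code{qc},
#'   \code{files}.
#' @export
run_compare <- function(map, counts, sheet, condition_pair, out_dir,
                        cfg = run_config(), condition_by = "genotype_time") {
  .ensure_dir(out_dir)
  qcres <- .apply_qc(map, counts, cfg)
  sheet2 <- sheet[sheet$sample_id %in% qcres$keep, , drop = FALSE]
  class(sheet2) <- c("sample_sheet", "data.frame")
  cond <- sheet_conditions(sheet2, by = condition_by)
  missing_lev <- setdiff(condition_pair, levels(cond))
  if (length(missing_lev))
    stop(sprintf("unknown condition label(s): %s",
                 paste(missing_lev, collapse = ", ")))
  keep_rows <- cond %in% condition_pair
  sheet2 <- sheet2[keep_rows, , drop = FALSE]
  class(sheet2) <- c("sample_sheet", "data.frame")
  counts2 <- counts[, sheet2$sample_id, drop = FALSE]
  profile <- smooth_profile(counts2, map, sheet2, condition_by = condition_by,
                            scheme = weight_scheme(cfg$sigma), p = cfg$p,
                            n_flank = cfg$n_flank)
  l1 <- condition_pair[1L]; l2 <- condition_pair[2L]
  keepf <- !profile$mask & is.finite(profile$se[, l1]) &
    is.finite(profile$se[, l2])
  cmp <- compare_conditions(profile$b[keepf, l1], profile$b[keepf, l2],
                            profile$se[keepf, l1], profile$se[keepf, l2],
                            df = profile$eff_df[keepf],
                            cov12 = profile$cov_b[keepf, l1, l2])
  res <- cbind(map[keepf, c("chrom", "start", "end", "id")], cmp)
  rownames(res) <- NULL
  files <- c(results = file.path(out_dir, "comparison.tsv"),
             z = file.path(out_dir, "zscore.bedGraph"),
             p = file.path(out_dir, "pvalue.bedGraph"))
  utils::write.table(res, files["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bedgraph(res$chrom, res$start, res$end, res$z, files["z"])
  write_bedgraph(res$chrom, res$start, res$end, res$p, files["p"])
  .write_resolved_config(cfg, out_dir,
                         extra = list(condition_pair = condition_pair))
  invisible(list(results = res, profile = profile, qc = qcres$qc,
                 files = files))
}

#' Run the track-rhythm pipeline on binned temporal tracks
#'
#' @param tracks A \code{binned_track_set} (see
#'   \code{\link{track_rhythm_analysis}}).
#' @param out_dir Output directory.
#' @param cfg A \code{\link{run_config}}.
#' @return Invisibly, a list: \code{results}, \code{files}.
#' @export
run_track_rhythm <- function(tracks, out_dir, cfg = run_config()) {
  .ensure_dir(out_dir)
  if (length(unique(tracks$time)) < 3)
    stop("at least 3 time-point tracks are required")
  pcol <- color_params(cfg$hill_n, cfg$k_a, cfg$k_p)
  res <- track_rhythm_analysis(tracks, half_width = cfg$smooth_half_width,
                               params = pcol)
  files <- c(results = file.path(out_dir, "track_rhythms.tsv"),
             colors = file.path(out_dir, "track_peak_time.bed"))
  utils::write.table(res, files["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_color_track(res$chrom, res$start, res$end, res$color, res$brightness,
                    files["colors"])
  .write_resolved_config(cfg, out_dir)
  invisible(list(results = res, files = files))
}
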