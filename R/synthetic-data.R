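#' Simulation configuration for a synthetic 4C-seq experiment
#'
#' Bundles the parameters of the in-silico restriction digest, the
#' bait-centred distance-decay contact background and the count-sampling
#' noise model. Defaults emulate a liver time-course design: six time points
#' 4 h apart over one diurnal cycle, three replicates, a DpnII-like fragment
#' map (~500 bp fragments) and moderate replicate overdispersion.
#'
#' @param chrom_length Chromosome length in bp.
#' @param mean_fragment_length Mean restriction-fragment length in bp.
#' @param bait_position Bait position in bp; defaults to the chromosome
#'   midpoint.
#' @param n_timepoints Number of time points (4 h spacing).
#' @param n_replicates Replicates per condition.
#' @param reads_per_sample Sequenced cis reads per library.
#' @param decay_scale Distance scale of the contact-decay background, bp.
#' @param decay_exponent Power-law exponent of the decay.
#' @param dispersion Gamma overdispersion of per-fragment rates across
#'   replicates (0 = pure multinomial sampling; variance of the rate
#'   multiplier equals \code{dispersion}).
#' @param rng_seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(chrom_length = 2e6, mean_fragment_length = 500,
                       bait_position = NULL, n_timepoints = 6, n_replicates = 3,
                       reads_per_sample = 1e5, decay_scale = 1e4,
                       decay_exponent = 1, dispersion = 0.05, rng_seed = 1L) {
  chrom_length <- as.numeric(chrom_length)
  mean_fragment_length <- as.numeric(mean_fragment_length)
  reads_per_sample <- as.numeric(reads_per_sample)
  decay_scale <- as.numeric(decay_scale)
  decay_exponent <- as.numeric(decay_exponent)
  dispersion <- as.numeric(dispersion)
  if (is.null(bait_position)) bait_position <- chrom_length / 2
  bait_position <- as.numeric(bait_position)
  cfg <- list(chrom_length = chrom_length,
              mean_fragment_length = mean_fragment_length,
              bait_position = bait_position,
              n_timepoints = n_timepoints,
              n_replicates = n_replicates,
              reads_per_sample = reads_per_sample,
              decay_scale = decay_scale,
              decay_exponent = decay_exponent,
              dispersion = dispersion,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (chrom_length <= 0 || mean_fragment_length <= 0 || reads_per_sample <= 0)
      stop("chrom_length, mean_fragment_length and reads_per_sample must be positive")
    if (chrom_length < 2 * mean_fragment_length)
      stop("chrom_length must be at least twice the mean fragment length")
    if (bait_position < 0 || bait_position >= chrom_length)
      stop("bait_position outside the chromosome")
    if (dispersion < 0) stop("dispersion must be non-negative")
    if (n_timepoints > 1 && (n_timepoints - 1) * 4 > 24)
      stop("time points at 4 h spacing must span at most 24 h")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' A planted interaction peak
#'
#' Describes one promoter--enhancer-like contact planted on top of the
#' distance-decay background: a Gaussian enrichment bump whose strength is
#' either constant in time (a stable loop) or modulated by a 24-h cosine (an
#' oscillating loop).
#'
#' @param center Peak centre, bp.
#' @param width Gaussian standard deviation of the enrichment bump, bp.
#' @param fold Baseline enrichment over background at the peak centre
#'   (\code{>= 1}; 1 means no peak).
#' @param rel_amplitude Relative amplitude of the temporal cosine modulation
#'   in \code{[0, 1)}; 0 gives a stable loop.
#' @param peak_time ZT hour at which contact is maximal.
#' @return A list of class \code{planted_peak}.
#' @export
planted_peak <- function(center, width = 2000, fold = 3, rel_amplitude = 0,
                         peak_time = 0) {
  if (fold < 1) stop("'fold' must be >= 1")
  if (rel_amplitude < 0 || rel_amplitude >= 1)
    stop("'rel_amplitude' must lie in [0, 1)")
  if (width <= 0) stop("'width' must be positive")
  structure(list(center = center, width = width, fold = fold,
                 rel_amplitude = rel_amplitude, peak_time = peak_time %% 24),
            class = "planted_peak")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.digest_impl <- function(config) {
  m <- config$mean_fragment_length
  L <- config$chrom_length
  # draw in chunks until the cuts cover the chromosome
  lens <- numeric(0)
  while (sum(lens) < L) {
    k <- max(16L, ceiling((L - sum(lens)) / m) + 8L)
    lens <- c(lens, pmax(50, round(stats::rexp(k, rate = 1 / m))))
  }
  ends <- cumsum(lens)
  ends <- c(ends[ends < L], L)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  bait <- findInterval(config$bait_position, starts)
  map <- fragment_map("chrS", starts, ends, bait_index = bait)
  map
}

#' Digest a synthetic chromosome into restriction fragments
#'
#' Fragment lengths are i.i.d. exponential with the configured mean,
#' truncated below at 50 bp (restriction sites closer than that are treated
#' as a single cut, as very short fragments are unmappable in practice). The
#' fragment containing \code{bait_position} is flagged as the bait.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{\link{fragment_map}} tiling \code{[0, chrom_length)}.
#' @examples
#' map <- digest_chromosome(sim_config(chrom_length = 1e4, rng_seed = 7))
#' sum(map$end - map$start)  # == chrom_length
#' @export
digest_chromosome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, .digest_impl(config))
}

#' Expected contact profile at one time point
#'
#' The background contact frequency decays smoothly with distance d from the
#' bait as \code{(1 + |d|/decay_scale)^(-decay_exponent)}. Each planted peak
#' multiplies the background by
#' \code{1 + (fold - 1) * exp(-d_pk^2 / (2 width^2)) * (1 + rel_amplitude *
#' cos(2 pi (t - peak_time) / 24))}
#' where \code{d_pk} is the distance to the peak centre. The result is
#' normalized to a probability vector over the fragment map.
#'
#' @param map A \code{\link{fragment_map}} with a bait.
#' @param peaks List of \code{\link{planted_peak}} objects (possibly empty).
#' @param time ZT hour.
#' @param config A \code{\link{sim_config}} (decay parameters).
#' @return Numeric vector of per-fragment expected contact fractions, summing
#'   to 1.
#' @export
expected_profile <- function(map, peaks = list(), time = 0, config) {
  bi <- .require_bait(map)
  mid <- fragment_mid(map)
  d <- abs(mid - mid[bi])
  prof <- (1 + d / config$decay_scale)^(-config$decay_exponent)
  if (inherits(peaks, "planted_peak")) peaks <- list(peaks)
  for (pk in peaks) {
    mod <- 1 + pk$rel_amplitude * cos(2 * pi * (time - pk$peak_time) / 24)
    bump <- (pk$fold - 1) * exp(-(mid - pk$center)^2 / (2 * pk$width^2))
    prof <- prof * (1 + bump * mod)
  }
  prof / sum(prof)
}

.sample_counts_impl <- function(expected, config) {
  rate <- expected
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    rate <- expected * stats::rgamma(length(expected), shape = shape,
                                     scale = 1 / shape)
    s <- sum(rate)
    if (s <= 0) stop("degenerate rates: all gamma-perturbed rates are zero")
    rate <- rate / s
  }
  as.integer(stats::rmultinom(1L, size = config$reads_per_sample, prob = rate))
}

#' Sample fragment counts from an expected profile
#'
#' Counts follow a gamma-mixed multinomial: each fragment's rate is its
#' expected fraction times an independent gamma multiplier with mean 1 and
#' variance \code{dispersion}; the renormalized rates parameterize a
#' multinomial with \code{reads_per_sample} trials, so the library size is
#' conserved exactly. \code{dispersion = 0} degenerates to a plain
#' multinomial.
#'
#' @param expected Per-fragment expected fractions (must sum to 1).
#' @param config A \code{\link{sim_config}}; its \code{rng_seed} makes the
#'   draw reproducible.
#' @return Integer vector of counts summing to \code{reads_per_sample}.
#' @export
sample_counts <- function(expected, config) {
  if (any(expected < 0)) stop("expected fractions must be non-negative")
  if (abs(sum(expected) - 1) > 1e-8) stop("expected fractions must sum to 1")
  if (config$dispersion < 0) stop("dispersion must be non-negative")
  with_seed(config$rng_seed, .sample_counts_impl(expected, config))
}

#' Simulate a complete 4C-seq experiment with known ground truth
#'
#' Digests a chromosome, computes the expected contact profile of every
#' (genotype, time) condition and samples one count vector per sample-sheet
#' row. In knockout (\code{"KO"}) samples the temporal modulation of every
#' peak is switched off (\code{rel_amplitude = 0}) and the enrichment fold is
#' attenuated by \code{ko_fold_attenuation}, emulating a clock-impaired
#' condition in which loops persist but no longer oscillate.
#'
#' @param config A \code{\link{sim_config}}.
#' @param peaks List of \code{\link{planted_peak}} objects.
#' @param sheet A \code{\link{sample_sheet}}; times must be a subset of the
#'   4-h grid \code{{0, 4, ..., 20}}.
#' @param ko_fold_attenuation Multiplier applied to \code{fold - 1} in KO
#'   samples; 1 preserves the loop strength.
#' @return A list of class \code{fourc_sim} with elements \code{map}
#'   (\code{fragment_map}), \code{counts} (integer matrix fragments x
#'   samples), \code{sheet}, and \code{truth} (list with per-condition
#'   expected fractions and the planted peak table).
#' @export
simulate_experiment <- function(config, peaks = list(), sheet,
                                ko_fold_attenuation = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(sheet, "sample_sheet"))
  if (nrow(sheet) == 0L) stop("sample sheet is empty")
  if (!all(sheet$time %in% seq(0, 20, by = 4)))
    stop("sample times must lie on the 4-h grid {0, 4, ..., 20}")
  if (inherits(peaks, "planted_peak")) peaks <- list(peaks)
  with_seed(config$rng_seed, {
    map <- .digest_impl(config)
    conds <- unique(sheet[c("genotype", "time")])
    cond_key <- sprintf("%s_ZT%02d", conds$genotype, as.integer(conds$time))
    expected <- matrix(NA_real_, nrow(map), nrow(conds),
                       dimnames = list(map$id, cond_key))
    for (k in seq_len(nrow(conds))) {
      pk <- peaks
      if (conds$genotype[k] == "KO") {
        pk <- lapply(peaks, function(p) {
          planted_peak(p$center, p$width,
                       fold = 1 + (p$fold - 1) * ko_fold_attenuation,
                       rel_amplitude = 0, peak_time = p$peak_time)
        })
      }
      expected[, k] <- expected_profile(map, pk, conds$time[k], config)
    }
    counts <- matrix(0L, nrow(map), nrow(sheet),
                     dimnames = list(map$id, sheet$sample_id))
    key <- sprintf("%s_ZT%02d", sheet$genotype, as.integer(sheet$time))
    for (s in seq_len(nrow(sheet)))
      counts[, s] <- .sample_counts_impl(expected[, key[s]], config)
    peak_tab <- if (length(peaks)) {
      do.call(rbind, lapply(peaks, function(p)
        data.frame(center = p$center, width = p$width, fold = p$fold,
                   rel_amplitude = p$rel_amplitude, peak_time = p$peak_time)))
    } else {
      data.frame(center = numeric(0), width = numeric(0), fold = numeric(0),
                 rel_amplitude = numeric(0), peak_time = numeric(0))
    }
    structure(list(map = map, counts = counts, sheet = sheet,
                   truth = list(expected = expected, peaks = peak_tab)),
              class = "fourc_sim")
  })
}

#' Simulate cosine-modulated binned signal tracks
#'
#' Fixture generator for the track-rhythm module: a set of binned coverage
#' tracks (one per time point, log2 counts-per-million scale) whose value in
#' every bin follows \code{baseline + amplitude * cos(2 pi (t - peak_time) /
#' 24)} plus Gaussian noise. \code{amplitude}, \code{peak_time} and
#' \code{baseline} may be scalars or per-bin vectors, allowing spatially
#' varying phase patterns.
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width, bp.
#' @param timepoints ZT hours, one track per element.
#' @param amplitude Cosine amplitude (log2 CPM units).
#' @param peak_time ZT hour of maximal signal.
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline Mean level.
#' @param rng_seed Integer seed.
#' @return A data.frame of class \code{binned_track_set} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{time}, \code{value}.
#' @export
simulate_track <- function(n_bins, bin_size = 500,
                           timepoints = seq(0, 20, by = 4), amplitude = 1,
                           peak_time = 8, noise_sd = 0.1, baseline = 4,
                           rng_seed = 1L) {
  if (n_bins <= 0) stop("'n_bins' must be positive")
  amplitude <- rep_len(amplitude, n_bins)
  peak_time <- rep_len(peak_time, n_bins)
  baseline <- rep_len(baseline, n_bins)
  starts <- (seq_len(n_bins) - 1) * bin_size
  with_seed(rng_seed, {
    out <- do.call(rbind, lapply(timepoints, function(t) {
      v <- baseline + amplitude * cos(2 * pi * (t - peak_time) / 24)
      if (noise_sd > 0) v <- v + stats::rnorm(n_bins, sd = noise_sd)
      data.frame(chrom = "chrS", start = starts, end = starts + bin_size,
                 time = t, value = v)
    }))
    class(out) <- c("binned_track_set", "data.frame")
    out
  })
}
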