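test_that("digestion tiles the chromosome exactly and is seed-deterministic", {
  cfg <- sim_config(chrom_length = 10000, mean_fragment_length = 500,
                    rng_seed = 3)
  map <- digest_chromosome(cfg)
  expect_equal(map$start[1], 0)
  expect_equal(map$end[nrow(map)], 10000)
  expect_equal(sum(map$end - map$start), 10000)
  expect_true(all(map$start[-1] == map$end[-nrow(map)])) # contiguous
  expect_identical(map, digest_chromosome(cfg))
  # bait fragment contains the bait position
  bi <- bait_index(map)
  expect_true(map$start[bi] <= cfg$bait_position &&
              cfg$bait_position < map$end[bi])
  expect_error(digest_chromosome(sim_config(chrom_length = 900,
                                            mean_fragment_length = 500)),
               "twice")
})

test_that("fragment lengths follow the configured exponential mean", {
  cfg <- sim_config(chrom_length = 2e6, mean_fragment_length = 500,
                    rng_seed = 17)
  map <- digest_chromosome(cfg)
  lens <- map$end - map$start
  expect_gt(nrow(map), 1000)
  expect_lt(abs(mean(lens) - 500) / 500, 0.10)
  expect_true(all(lens[-nrow(map)] >= 50))
})

test_that("expected profile decays monotonically away from the bait", {
  cfg <- sim_config(chrom_length = 5e4, bait_position = 2.5e4, rng_seed = 1)
  map <- digest_chromosome(cfg)
  prof <- expected_profile(map, list(), time = 0, config = cfg)
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  bi <- bait_index(map)
  expect_true(all(diff(prof[seq_len(bi)]) > 0))        # rising to the bait
  expect_true(all(diff(prof[bi:nrow(map)]) < 0))       # falling after it
})

test_that("stable peaks are time-invariant and fold = 1 peaks are inert", {
  cfg <- sim_config(chrom_length = 1e5, rng_seed = 2)
  map <- digest_chromosome(cfg)
  stable <- planted_peak(center = 7e4, fold = 4, rel_amplitude = 0)
  expect_identical(expected_profile(map, stable, 8, cfg),
                   expected_profile(map, stable, 20, cfg))
  inert <- planted_peak(center = 7e4, fold = 1, rel_amplitude = 0)
  expect_equal(expected_profile(map, inert, 0, cfg),
               expected_profile(map, list(), 0, cfg))
})

test_that("rhythmic peak modulation matches direct evaluation of the formula", {
  cfg <- sim_config(chrom_length = 1e5, bait_position = 5e4, rng_seed = 2)
  map <- digest_chromosome(cfg)
  pk <- planted_peak(center = 7e4, width = 1500, fold = 3,
                     rel_amplitude = 0.5, peak_time = 16)
  at16 <- expected_profile(map, pk, 16, cfg)
  at04 <- expected_profile(map, pk, 4, cfg)
  # direct formula evaluation at every fragment midpoint (independent oracle)
  mid <- fragment_mid(map)
  bg <- (1 + abs(mid - mid[bait_index(map)]) / cfg$decay_scale)^(-cfg$decay_exponent)
  bump <- (pk$fold - 1) * exp(-(mid - pk$center)^2 / (2 * pk$width^2))
  for (tt in c(16, 4)) {
    mod <- 1 + pk$rel_amplitude * cos(2 * pi * (tt - pk$peak_time) / 24)
    direct <- bg * (1 + bump * mod)
    direct <- direct / sum(direct)
    got <- if (tt == 16) at16 else at04
    expect_equal(got, direct, tolerance = 1e-12)
  }
  # enrichment at the peak centre is stronger at ZT16 than at the trough side
  ctr <- which.min(abs(mid - pk$center))
  expect_gt(at16[ctr] / at04[ctr], 1)
})

test_that("count sampling conserves the library size and the seed", {
  cfg <- sim_config(chrom_length = 5e4, reads_per_sample = 12345,
                    dispersion = 0.1, rng_seed = 9)
  map <- digest_chromosome(cfg)
  prof <- expected_profile(map, list(), 0, cfg)
  cts <- sample_counts(prof, cfg)
  expect_equal(sum(cts), 12345)
  expect_identical(cts, sample_counts(prof, cfg))
  expect_error(sample_counts(prof * 2, cfg), "sum to 1")
})

test_that("multinomial sampling matches the binomial-sd oracle", {
  # dispersion = 0, uniform fractions over 100 fragments, 1e6 reads:
  # each count is Binomial(1e6, 0.01), sd = sqrt(1e6 * 0.01 * 0.99)
  cfg <- sim_config(chrom_length = 1e5, reads_per_sample = 1e6,
                    dispersion = 0, rng_seed = 21)
  frac <- rep(1 / 100, 100)
  cts <- sample_counts(frac, cfg)
  sd_binom <- sqrt(1e6 * 0.01 * 0.99)
  expect_true(all(abs(cts - 1e4) < 5 * sd_binom))
  cfg_bad <- cfg; cfg_bad$dispersion <- -1
  expect_error(sample_counts(frac, cfg_bad), "non-negative")
})

test_that("overdispersion inflates replicate variance beyond multinomial", {
  cfg0 <- sim_config(chrom_length = 2e4, mean_fragment_length = 1000,
                     reads_per_sample = 1e5, dispersion = 0.2, rng_seed = 1)
  map <- digest_chromosome(cfg0)
  prof <- expected_profile(map, list(), 0, cfg0)
  draws <- sapply(seq_len(200), function(i) {
    cfg_i <- cfg0; cfg_i$rng_seed <- 1000L + i
    sample_counts(prof, cfg_i)
  })
  v_emp <- apply(draws, 1, var)
  v_multinom <- 1e5 * prof * (1 - prof)
  top <- order(prof, decreasing = TRUE)[1:5]
  expect_true(all(v_emp[top] > 1.5 * v_multinom[top]))
})

test_that("simulate_experiment bookkeeping, KO flattening and truth sums", {
  cfg <- sim_config(chrom_length = 8e4, n_replicates = 2,
                    reads_per_sample = 2e4, rng_seed = 4)
  pk <- planted_peak(center = 6e4, fold = 3, rel_amplitude = 0.4,
                     peak_time = 12)
  sheet <- sample_sheet_grid(genotypes = c("WT", "KO"),
                             times = seq(0, 20, 4), n_replicates = 2)
  x <- simulate_experiment(cfg, pk, sheet)
  expect_equal(ncol(x$counts), nrow(sheet))       # 24 samples
  expect_true(all(colSums(x$counts) == 2e4))
  expect_equal(unname(colSums(x$truth$expected)),
               rep(1, ncol(x$truth$expected)), tolerance = 1e-12)
  # KO profiles carry no temporal modulation; WT ones do
  ko <- x$truth$expected[, grep("^KO", colnames(x$truth$expected))]
  wt <- x$truth$expected[, grep("^WT", colnames(x$truth$expected))]
  expect_lt(max(apply(ko, 1, function(z) diff(range(z)))), 1e-15)
  expect_gt(max(apply(wt, 1, function(z) diff(range(z)))), 0)
  expect_error(simulate_experiment(cfg, pk, sheet[0, ]), "empty")
})

test_that("stable peaks give genotype-identical expected profiles", {
  cfg <- sim_config(chrom_length = 8e4, n_replicates = 1, rng_seed = 6)
  pk <- planted_peak(center = 6e4, fold = 3, rel_amplitude = 0)
  sheet <- sample_sheet_grid(genotypes = c("WT", "KO"), times = c(8, 20),
                             n_replicates = 1)
  x <- simulate_experiment(cfg, pk, sheet, ko_fold_attenuation = 1)
  e <- x$truth$expected
  expect_equal(e[, "WT_ZT08"], e[, "KO_ZT08"])
  expect_equal(e[, "WT_ZT20"], e[, "KO_ZT20"])
})

test_that("simulated tracks obey the cosine model", {
  # noiseless, amplitude 1, peak at ZT12: ZT12 minus ZT0 spans the full range
  tr <- simulate_track(n_bins = 10, timepoints = c(0, 12), amplitude = 1,
                       peak_time = 12, noise_sd = 0, baseline = 4)
  v0 <- tr$value[tr$time == 0]
  v12 <- tr$value[tr$time == 12]
  expect_equal(v12 - v0, rep(2, 10))
  flat <- simulate_track(n_bins = 5, amplitude = 0, noise_sd = 0)
  expect_equal(diff(range(flat$value)), 0)
  expect_identical(simulate_track(20, rng_seed = 5),
                   simulate_track(20, rng_seed = 5))
})

test_that("harmonic fit recovers noiseless planted track parameters exactly", {
  tr <- simulate_track(n_bins = 4, timepoints = seq(0, 20, 4),
                       amplitude = 0.8, peak_time = 14.5, noise_sd = 0,
                       baseline = 3)
  times <- sort(unique(tr$time))
  M <- sapply(times, function(t) tr$value[tr$time == t])
  fit <- harmonic_fit(M, times)
  expect_equal(fit$amplitude, rep(0.8, 4), tolerance = 1e-9)
  expect_equal(fit$peak_time, rep(14.5, 4), tolerance = 1e-9)
})
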