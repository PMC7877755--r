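test_that("cis normalization returns proportions and respects the mask", {
  cts <- matrix(c(2L, 3L, 5L), ncol = 1, dimnames = list(NULL, "s1"))
  expect_equal(drop(normalize_cis(cts)), c(0.2, 0.3, 0.5),
               ignore_attr = TRUE)
  expect_equal(normalize_cis(cts * 10L), normalize_cis(cts))  # scale invariant
  cts2 <- matrix(c(100L, 1L, 1L), ncol = 1)
  frac <- drop(normalize_cis(cts2, mask = c(TRUE, FALSE, FALSE)))
  expect_equal(frac, c(0, 0.5, 0.5), ignore_attr = TRUE)
  expect_error(normalize_cis(matrix(0L, 3, 1), mask = rep(FALSE, 3)),
               "no unmasked counts")
})

test_that("variance stabilization has its closed-form values", {
  expect_equal(variance_stabilize(0), 0)
  expect_equal(variance_stabilize(1 / 500), log10(2))
  expect_gt(variance_stabilize(0.002), variance_stabilize(0.001))
  expect_error(variance_stabilize(-0.1), "non-negative")
})

test_that("Gaussian weight matches its closed form and truncates", {
  sch <- weight_scheme(2500)
  expect_equal(gaussian_weight(0, sch), 1)
  expect_equal(gaussian_weight(2500, sch), exp(-0.5))
  expect_equal(gaussian_weight(10001, sch), 0)   # beyond 4 sigma
  expect_gt(gaussian_weight(10000, sch), 0)
  expect_error(weight_scheme(2500, truncation_radius = 3000), "2 \\* sigma")
})

test_that("condition weight is the nonzero-replicate fraction", {
  expect_equal(condition_weight(c(4L, 1L)), 1)
  expect_equal(condition_weight(c(4L, 0L)), 0.5)
  expect_equal(condition_weight(c(0L, 0L, 0L)), 0)
  expect_error(condition_weight(integer(0)), "no replicates")
})

test_that("constant data yield zero condition effects and zero residuals", {
  map <- tiny_map(15)
  cond <- factor(rep(c("A", "B", "C"), each = 2))
  Y <- matrix(0.7, 15, 6)
  counts <- matrix(1L, 15, 6)
  fit <- fit_lwmr(Y, map, cond, position = 3000, counts = counts)
  expect_equal(unname(fit$b), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$sigma2, 0, tolerance = 1e-14)
  expect_equal(unname(fit$fitted), rep(0.7, 3), tolerance = 1e-12)
})

test_that("a single-fragment window collapses to the replicate mean", {
  map <- tiny_map(3, len = 50000)    # fragments far apart
  cond <- factor(c("A", "A", "A"))
  Y <- matrix(c(1, 2, 6), 3, 3, byrow = FALSE)
  Y[] <- c(1, 2, 6, 2, 3, 7, 3, 4, 8)   # fragments x replicates
  counts <- matrix(1L, 3, 3)
  sch <- weight_scheme(2500)           # 10 kb truncation < 50 kb spacing
  fit <- fit_lwmr(Y, map, cond, position = fragment_mid(map)[2],
                  scheme = sch, counts = counts)
  expect_equal(length(fit$window), 1L)
  expect_equal(unname(fit$a), mean(Y[2, ]))
})

test_that("the local solver equals the dense weighted-least-squares oracle", {
  for (seed in 1:25) {
    inst <- random_lwmr_instance(n_frag = sample(8:30, 1),
                                 n_cond = sample(2:6, 1),
                                 n_rep = sample(2:3, 1), seed = seed)
    fit <- fit_lwmr(inst$Y, inst$map, inst$cond, inst$position,
                    inst$scheme, counts = inst$counts)
    orc <- lwmr_dense_oracle(inst$Y, inst$counts, inst$map, inst$cond,
                             inst$position, inst$scheme)
    expect_lt(max(abs(fit$b - orc$b)), 1e-8)
    expect_lt(max(abs(fit$a - orc$a), na.rm = TRUE), 1e-8)
  }
})

test_that("condition contrasts are invariant to the identifiability choice", {
  inst <- random_lwmr_instance(20, 4, 2, seed = 99)
  fit <- fit_lwmr(inst$Y, inst$map, inst$cond, inst$position, inst$scheme,
                  counts = inst$counts)
  ref <- lwmr_dense_oracle(inst$Y, inst$counts, inst$map, inst$cond,
                           inst$position, inst$scheme, coding = "treatment")
  d_fit <- outer(fit$b, fit$b, "-")
  d_ref <- outer(ref$b, ref$b, "-")
  expect_lt(max(abs(d_fit - d_ref)), 1e-8)
})

test_that("adding a constant shifts fragment effects, not condition effects", {
  inst <- random_lwmr_instance(18, 3, 2, seed = 7)
  f0 <- fit_lwmr(inst$Y, inst$map, inst$cond, inst$position, inst$scheme,
                 counts = inst$counts)
  f1 <- fit_lwmr(inst$Y + 2.5, inst$map, inst$cond, inst$position,
                 inst$scheme, counts = inst$counts)
  expect_equal(f1$b, f0$b, tolerance = 1e-10)
  expect_equal(f1$a, f0$a + 2.5, tolerance = 1e-10)
})

test_that("noiseless additive data are recovered exactly at any bandwidth", {
  set.seed(31)
  n <- 25
  map <- tiny_map(n)
  cond <- factor(rep(c("A", "B", "C", "D"), each = 2))
  a_true <- runif(n, 0.5, 2)
  b_true <- c(0.3, -0.1, -0.4, 0.2)    # sums to zero
  Y <- outer(a_true, b_true[as.integer(cond)], "+")
  counts <- matrix(1L, n, 8)
  for (sg in c(600, 2500, 6000)) {
    fit <- fit_lwmr(Y, map, cond, position = 5000,
                    scheme = weight_scheme(sg), counts = counts)
    expect_equal(unname(fit$b), b_true, tolerance = 1e-10)
    expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  }
})

test_that("fragments beyond the truncation radius have no influence", {
  inst <- random_lwmr_instance(30, 3, 2, seed = 12)
  fit0 <- fit_lwmr(inst$Y, inst$map, inst$cond, inst$position, inst$scheme,
                   counts = inst$counts)
  mid <- fragment_mid(inst$map)
  far <- abs(mid - inst$position) > inst$scheme$truncation_radius
  skip_if(!any(far))
  Y2 <- inst$Y; Y2[far, ] <- Y2[far, ] + 100
  c2 <- inst$counts; c2[far, ] <- c2[far, ] + 50L
  fit1 <- fit_lwmr(Y2, inst$map, inst$cond, inst$position, inst$scheme,
                   counts = c2)
  expect_identical(fit0$b, fit1$b)
  expect_identical(fit0$se_b, fit1$se_b)
})

test_that("a condition with no weight in the window is flagged, not silent", {
  map <- tiny_map(10)
  cond <- factor(rep(c("A", "B"), each = 2))
  counts <- matrix(c(rep(3L, 20), rep(0L, 20)), 10, 4)  # B all zero
  Y <- matrix(runif(40), 10, 4); Y[counts == 0] <- 0
  fit <- fit_lwmr(Y, map, cond, position = 2000, counts = counts)
  expect_true(fit$degenerate[["B"]])
  expect_true(is.na(fit$b[["B"]]))
  expect_false(fit$degenerate[["A"]])
})

test_that("smooth_profile agrees with per-position fit_lwmr", {
  cfg <- sim_config(chrom_length = 4e4, bait_position = 2e4,
                    n_replicates = 2, reads_per_sample = 2e4, rng_seed = 13)
  sheet <- sample_sheet_grid(times = c(0, 8, 16), n_replicates = 2)
  x <- simulate_experiment(cfg, list(), sheet)
  prof <- smooth_profile(x$counts, x$map, x$sheet, condition_by = "time")
  mask <- prof$mask
  frac <- normalize_cis(x$counts, mask)
  Y <- variance_stabilize(frac)
  cond <- sheet_conditions(x$sheet, "time")
  q <- which(!mask)[5]
  fit <- fit_lwmr(Y, x$map, cond, fragment_mid(x$map)[q], mask = mask,
                  counts = x$counts)
  expect_equal(unname(prof$b[q, ]), unname(fit$b), tolerance = 1e-12)
  expect_equal(unname(prof$se[q, ]), unname(fit$se_b), tolerance = 1e-12)
  expect_equal(prof$a[q], unname(fit$a[x$map$id[q]]), tolerance = 1e-12)
  # masked fragments carry no estimates
  expect_true(all(is.na(prof$b[mask, ])))
})
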