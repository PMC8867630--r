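test_that("cohort bookkeeping, determinism, and invariants hold", {
  co <- simulate_cohort(n_hc = 100, n_asd = 100, seed = 3)
  expect_equal(nrow(co), 200)
  expect_length(grep("^roi_", names(co)), 142)
  expect_true(all(co$tiv > 0))
  expect_true(all(is.na(co$true_subtype[co$diagnosis == "control"])))
  expect_true(all(!is.na(co$true_subtype[co$diagnosis == "patient"])))
  expect_equal(length(unique(co$site)), 7)

  # identical regeneration under the same seed; different noise otherwise
  co2 <- simulate_cohort(n_hc = 100, n_asd = 100, seed = 3)
  expect_identical(co, co2)
  co3 <- simulate_cohort(n_hc = 100, n_asd = 100, seed = 4)
  expect_false(identical(co$roi_001, co3$roi_001))

  expect_error(simulate_cohort(n_hc = 0), "positive")
  expect_error(simulate_cohort(subtype_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(simulate_cohort(affected_fraction = 1.5), "affected_fraction")
})

test_that("planted subtype means match the generative model", {
  # subtype-1 mean on an affected feature = baseline + d * noise_sd
  # (age and site cancel in expectation against controls at matched design)
  co <- small_cohort(seed = 7, n_hc = 300, n_asd = 300, d = 0.8,
                     n_features = 40)
  aff <- attr(co, "affected_features")
  gen <- attr(co, "generator")
  f <- aff[1]
  s1 <- co[[f]][co$diagnosis == "patient" & co$true_subtype == 1]
  hc <- co[[f]][co$diagnosis == "control"]
  shift_hat <- mean(s1) - mean(hc)
  expected <- gen$effect_size_d * gen$noise_sd
  se <- sqrt(var(s1) / length(s1) + var(hc) / length(hc))
  expect_lt(abs(shift_hat - expected), 3 * se)

  # unaffected features carry no shift
  un <- setdiff(grep("^roi_", names(co), value = TRUE), aff)[1]
  s1u <- co[[un]][co$diagnosis == "patient" & co$true_subtype == 1]
  hcu <- co[[un]][co$diagnosis == "control"]
  seu <- sqrt(var(s1u) / length(s1u) + var(hcu) / length(hcu))
  expect_lt(abs(mean(s1u) - mean(hcu)), 4 * seu)
})

test_that("with no planted effect, subtype t-tests reject at the nominal rate", {
  co <- simulate_cohort(n_hc = 20, n_asd = 200, n_features = 142,
                        effect_size_d = 0, seed = 11)
  pat <- co[co$diagnosis == "patient", ]
  p <- vapply(grep("^roi_", names(co), value = TRUE), function(f) {
    two_sample_t(pat[[f]][pat$true_subtype == 1],
                 pat[[f]][pat$true_subtype == 2])$p_value
  }, numeric(1))
  hits <- sum(p < 0.05)
  # binomial 99% envelope around alpha = 0.05 at 142 features
  bounds <- qbinom(c(0.005, 0.995), 142, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("oracle recovers planted labels under the stated conditions", {
  co <- simulate_cohort(n_hc = 100, n_asd = 100, effect_size_d = 0.8,
                        affected_fraction = 0.6, seed = 9)
  lab <- oracle_subtype_labels(co)
  truth <- co$true_subtype[co$diagnosis == "patient"]
  agreement <- max(mean(lab == truth), mean(lab != truth))
  expect_gte(agreement, 0.95)
})

test_that("clinical scores track configured means and TIV correlations", {
  co <- simulate_cohort(n_hc = 600, n_asd = 600, seed = 21)
  s1 <- co[co$diagnosis == "patient" & co$true_subtype == 1, ]
  s2 <- co[co$diagnosis == "patient" & co$true_subtype == 2, ]
  spec <- default_clinical_spec()
  m1 <- spec$mean[spec$score == "fiq" & spec$group == "subtype1"]
  m2 <- spec$mean[spec$score == "fiq" & spec$group == "subtype2"]
  expect_lt(abs(mean(s1$fiq) - m1), 3 * sd(s1$fiq) / sqrt(nrow(s1)) + 0.06)
  expect_lt(abs(mean(s2$fiq) - m2), 3 * sd(s2$fiq) / sqrt(nrow(s2)) + 0.06)

  # configured TIV correlations within +-0.1, Monte-Carlo over seeds
  rs <- sapply(22:24, function(sd_) {
    ci <- simulate_cohort(n_hc = 50, n_asd = 1000, seed = sd_)
    g1 <- ci[ci$diagnosis == "patient" & ci$true_subtype == 1, ]
    g2 <- ci[ci$diagnosis == "patient" & ci$true_subtype == 2, ]
    c(pearson_r(g1$tiv, g1$piq)$estimate,
      pearson_r(g2$tiv, g2$ados_comm)$estimate,
      pearson_r(g1$tiv, g1$ados_comm)$estimate)
  })
  expect_lt(abs(mean(rs[1, ]) - 0.24), 0.1)
  expect_lt(abs(mean(rs[2, ]) - 0.235), 0.1)
  expect_lt(abs(mean(rs[3, ])), 0.1)
})

test_that("dynamic series respect coupling limits and determinism", {
  co <- small_cohort(n_hc = 4, n_asd = 4, n_sites = 2, n_features = 10)
  # coupling 1, no noise: VMHC of every pair is 1 in every window
  ser <- simulate_timeseries(co, n_parcels = 10, n_timepoints = 60,
                             coupling = 1, noise_sd = 0,
                             modulation = list(control = c(0, 0),
                                               subtype1 = c(0, 0),
                                               subtype2 = c(0, 0)),
                             seed = 2)
  maps <- windowed_measures(ser[[1]], window_length = 20, window_step = 10)
  expect_true(all(abs(maps$vmhc - 1) < 1e-10))

  # coupling 0 and no shared global course: mean VMHC is near 0
  ser0 <- simulate_timeseries(co, n_parcels = 20, n_timepoints = 120,
                              coupling = 0, noise_sd = 1,
                              modulation = list(control = c(0, 0),
                                                subtype1 = c(0, 0),
                                                subtype2 = c(0, 0)),
                              seed = 3)
  vm <- unlist(lapply(ser0, function(s) {
    m <- windowed_measures(s, window_length = 30, window_step = 10)$vmhc
    m[!is.na(m)]
  }))
  expect_lt(abs(mean(vm)), 3 / sqrt(length(vm) / 2))

  # determinism
  a <- simulate_timeseries(co, seed = 5)
  b <- simulate_timeseries(co, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_timeseries(co, n_timepoints = 10,
                                   block_length = 30), "block")
})

test_that("time series round-trip through CSV + JSON sidecars", {
  co <- small_cohort(n_hc = 2, n_asd = 2, n_sites = 2, n_features = 5)
  ser <- simulate_timeseries(co, n_parcels = 6, n_timepoints = 40,
                             block_length = 20, seed = 4)
  dir <- withr::local_tempdir()
  write_timeseries(ser, dir)
  back <- read_timeseries(dir)
  expect_setequal(names(back), names(ser))
  s0 <- ser[[1]]
  b0 <- back[[s0$subject_id]]
  expect_equal(unname(b0$mat), unname(s0$mat), tolerance = 1e-12)
  expect_equal(b0$homotopic_pairs, s0$homotopic_pairs, ignore_attr = TRUE)
  expect_equal(b0$tr, s0$tr)
})
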