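test_that("motion filter applies the 2 mm / 2 deg rule inclusively", {
  df <- tibble::tibble(subject_id = sprintf("s%d", 1:3),
                       max_translation_mm = c(1.9, 2.0, 2.1),
                       max_rotation_deg = 0)
  kept <- motion_filter(df)
  expect_identical(kept$subject_id, c("s1", "s2"))

  expect_equal(nrow(motion_filter(df[0, ])), 0)

  withr::with_seed(3, {
    d10 <- tibble::tibble(
      subject_id = sprintf("s%d", 1:10),
      max_translation_mm = c(runif(7, 0, 1.8), 2.5, 0.3, 0.1),
      max_rotation_deg = c(runif(8, 0, 1.8), 3.1, 2.4))
  })
  kept10 <- motion_filter(d10)
  expect_equal(nrow(kept10), 7)
  log <- attr(kept10, "exclusion_log")
  expect_equal(log$n[log$reason == "excess_motion"], 3L)

  d10$max_rotation_deg[1] <- NA
  expect_warning(k2 <- motion_filter(d10), "motion metadata")
  expect_equal(nrow(k2), 6)
})

test_that("window grids cover the stated counts", {
  expect_length(make_windows(100, 30, 10), 8)
  expect_length(make_windows(30, 30, 5), 1)
  expect_length(make_windows(5, 2, 1), 4)
  w <- make_windows(100, 30, 10)
  expect_equal(w[[1]], 1:30)
  expect_equal(w[[8]], 71:100)
  expect_error(make_windows(10, 30), "length")
})

test_that("Kendall's W satisfies its closed-form identities", {
  # identical rankings
  expect_equal(kendalls_w(rbind(1:6, 1:6, 1:6)), 1)
  # m = 2 untied raters: W = (rho_spearman + 1) / 2
  withr::with_seed(8, {
    for (i in 1:10) {
      s <- rbind(sample(20), sample(20))
      expect_equal(kendalls_w(s),
                   (cor(s[1, ], s[2, ], method = "spearman") + 1) / 2,
                   tolerance = 1e-12)
    }
    # general identity on untied data
    for (i in 1:10) {
      m <- sample(3:6, 1)
      s <- t(replicate(m, sample(30)))
      expect_equal(kendalls_w(s), w_from_spearman(s), tolerance = 1e-12)
    }
  })
  # null expectation 1/m over many replicates
  withr::with_seed(9, {
    ws <- replicate(1000, kendalls_w(matrix(rnorm(4 * 20), 4, 20)))
  })
  expect_lt(abs(mean(ws) - 0.25), 0.01)
  # tie-corrected equals uncorrected on untied data (already via identity);
  # degenerate all-tied raters are rejected
  expect_error(kendalls_w(matrix(1, 3, 4)), "ties all items")
})

test_that("windowed measures hit their degenerate closed forms", {
  # all parcels share one identical course
  base <- sin(seq(0, 8 * pi, length.out = 60))
  mat <- matrix(rep(base, each = 6), 6, 60)
  ser <- toy_series(mat, pairs = cbind(1:3, 4:6))
  maps <- windowed_measures(ser, window_length = 20, window_step = 10,
                            reho_k = 2)
  expect_true(all(abs(maps$gscorr - 1) < 1e-8))
  expect_true(all(maps$dc == 5))
  expect_true(all(abs(maps$reho - 1) < 1e-8))
  expect_true(all(abs(maps$vmhc - 1) < 1e-8))

  # unpaired parcel: VMHC missing, other measures present
  ser2 <- toy_series(mat, pairs = cbind(1:2, 4:5))
  maps2 <- windowed_measures(ser2, window_length = 20, window_step = 10,
                             reho_k = 2)
  expect_true(all(is.na(maps2$vmhc[3, ])))
  expect_true(all(is.na(maps2$vmhc[6, ])))
  expect_true(all(!is.na(maps2$reho[3, ])))

  expect_error(windowed_measures(ser, window_length = 2), "3 timepoints")
})

test_that("null degree centrality matches the analytic tail probability", {
  p <- 30
  len <- 30
  withr::with_seed(21, {
    mat <- matrix(rnorm(p * 120), p, 120)
  })
  ser <- toy_series(mat, pairs = NULL)
  maps <- windowed_measures(ser, window_length = len, window_step = 30,
                            dc_threshold = 0.25)
  # null P(r > 0.25) at n = 30 via the exact t transform of r
  r0 <- 0.25
  t0 <- r0 * sqrt((len - 2) / (1 - r0^2))
  p_tail <- pt(t0, len - 2, lower.tail = FALSE)
  expected <- (p - 1) * p_tail
  se <- sqrt((p - 1) * p_tail * (1 - p_tail) / length(maps$dc))
  expect_lt(abs(mean(maps$dc) - expected), 4 * se + 0.15)
})

test_that("temporal SD has its closed form and reversal symmetry holds", {
  base <- matrix(rnorm(6 * 60), 6, 60)
  ser <- toy_series(base, pairs = cbind(1:3, 4:6))
  maps <- windowed_measures(ser, window_length = 20, window_step = 20,
                            reho_k = 2)
  tsd <- temporal_sd(maps)
  expect_true(all(tsd$sd >= 0, na.rm = TRUE))
  # two windows with values 0 and 2 -> sample SD sqrt(2)
  fake <- maps
  fake$reho[] <- rep(c(0, 2), each = 6)[seq_along(fake$reho)]
  fake$reho <- matrix(c(rep(0, 6), rep(2, 6)), 6, 2)
  fake$dc <- fake$gscorr <- fake$vmhc <- fake$reho
  expect_true(all(abs(temporal_sd(fake)$sd - sqrt(2)) < 1e-12))

  # time reversal: windows appear in reverse order with identical values
  rev_ser <- toy_series(base[, 60:1], pairs = cbind(1:3, 4:6))
  rmaps <- windowed_measures(rev_ser, window_length = 20, window_step = 20,
                             reho_k = 2)
  expect_equal(rmaps$gscorr, maps$gscorr[, 3:1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rmaps$vmhc, maps$vmhc[, 3:1], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("volume-wise concordance has the right limits", {
  # four identical measure maps -> W = 1 in every window, SD = 0
  m <- matrix(runif(10 * 4), 10, 4)
  maps <- structure(list(reho = m, dc = m, gscorr = m, vmhc = m,
                         window_length = 20, window_step = 10,
                         subject_id = "x"),
                    class = "polysub_dynmaps")
  conc <- volume_wise_concordance(maps)
  expect_true(all(abs(conc$per_window - 1) < 1e-12))
  expect_equal(conc$sd, 0)
  expect_equal(conc$mean, mean(conc$per_window))
  expect_equal(conc$sd, sd(conc$per_window))

  # independent measures: mean W near the null 1/m
  withr::with_seed(30, {
    ws <- replicate(60, {
      mm <- function() matrix(rnorm(142 * 1), 142, 1)
      maps0 <- structure(list(reho = mm(), dc = mm(), gscorr = mm(),
                              vmhc = mm(), window_length = 20,
                              window_step = 10, subject_id = "x"),
                         class = "polysub_dynmaps")
      volume_wise_concordance(maps0)$per_window
    })
  })
  expect_lt(abs(mean(ws) - 0.25), 0.02)
})

test_that("functional stability separates stationary from shuffled dynamics", {
  # noiseless block fixture: periodic latent courses whose period equals
  # the window stride, so every window sees an identical connectivity
  # profile (exactly time-invariant architecture)
  t_idx <- seq_len(160)
  ang <- 2 * pi * t_idx / 40
  latents <- rbind(sin(ang),
                   sin(ang + 0.9),
                   0.9 * cos(2 * ang) + 0.3 * sin(ang))
  withr::with_seed(40, {
    mat <- latents[rep(1:3, each = 6), ] +
      1e-6 * matrix(rnorm(18 * 160), 18)
  })
  ser <- toy_series(mat, pairs = NULL)
  stab <- functional_stability(ser, window_length = 40, window_step = 40,
                               atlas_groups = rep(1:3, each = 6))
  expect_equal(nrow(stab), 18)
  expect_true(all(stab$stability > 0.9))

  # connectivity re-randomized per window: near the null 1/n_windows
  withr::with_seed(41, {
    n_win <- 6
    mat2 <- do.call(cbind, lapply(seq_len(n_win), function(w) {
      l <- matrix(rnorm(3 * 20), 3, 20)
      l[sample(rep(1:3, each = 6)), ] + 0.05 * matrix(rnorm(18 * 20), 18)
    }))
  })
  ser2 <- toy_series(mat2, pairs = NULL)
  stab2 <- functional_stability(ser2, window_length = 20, window_step = 20,
                                atlas_groups = rep(1:3, each = 6))
  expect_lt(mean(stab2$stability), 2.5 / n_win)
})

test_that("planted subtype dynamics differences point the right way", {
  co <- small_cohort(seed = 51, n_hc = 10, n_asd = 40, n_features = 10)
  ser <- simulate_timeseries(co, n_parcels = 30, n_timepoints = 120, seed = 6)
  summ <- dynamic_summaries(ser, window_length = 30, window_step = 15)
  truth <- co$true_subtype[match(summ$subject_id, co$subject_id)]
  s1 <- summ[which(truth == 1), ]
  s2 <- summ[which(truth == 2), ]
  expect_gt(mean(s1$concordance_mean), mean(s2$concordance_mean))
  expect_lt(mean(s1$concordance_sd), mean(s2$concordance_sd))
  expect_lt(mean(s1$tsd_gscorr), mean(s2$tsd_gscorr))

  groups <- list(s1 = summ$subject_id[which(truth == 1)],
                 s2 = summ$subject_id[which(truth == 2)])
  cmp <- group_compare_dynamics(summ, co, groups)
  expect_gt(cmp$statistic[cmp$variable == "concordance_mean"], 0)
  expect_lt(cmp$statistic[cmp$variable == "concordance_sd"], 0)
  expect_equal(cmp$p_adjusted, bh_fdr(cmp$p_value)$p_adjusted)

  # permuting subject order leaves the tests unchanged
  perm <- withr::with_seed(1, sample(nrow(summ)))
  cmp2 <- group_compare_dynamics(summ[perm, ], co, groups)
  expect_equal(cmp$statistic, cmp2$statistic, tolerance = 1e-10)
})
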