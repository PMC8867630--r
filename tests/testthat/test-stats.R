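test_that("t-test, chi-square, correlation and FDR match base R on random draws", {
  withr::with_seed(50, {
    for (i in 1:50) {
      a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
      ours <- two_sample_t(a, b)
      ref <- t.test(a, b, var.equal = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
      oursw <- two_sample_t(a, b, equal_variance = FALSE)
      refw <- t.test(a, b)
      expect_equal(oursw$statistic, unname(refw$statistic), tolerance = 1e-8)
      expect_equal(oursw$df, unname(refw$parameter), tolerance = 1e-8)

      x <- rnorm(sample(5:30, 1))
      y <- x * runif(1, -1, 1) + rnorm(length(x))
      oursr <- pearson_r(x, y)
      refr <- cor.test(x, y)
      expect_equal(oursr$estimate, unname(refr$estimate), tolerance = 1e-8)
      expect_equal(oursr$p_value, refr$p.value, tolerance = 1e-8)

      p <- runif(sample(3:20, 1))
      expect_equal(bh_fdr(p)$p_adjusted, p.adjust(p, "BH"),
                   tolerance = 1e-12)

      tab_lab <- sample(1:2, 40, replace = TRUE)
      tab_site <- sample(letters[1:4], 40, replace = TRUE)
      tab_lab[1:2] <- 1:2
      tab_site[1:4] <- letters[1:4]
      oursc <- chi_square_site_composition(tab_lab, tab_site)
      refc <- suppressWarnings(chisq.test(table(tab_lab, tab_site),
                                          correct = FALSE))
      expect_equal(oursc$statistic, unname(refc$statistic), tolerance = 1e-8)
      expect_equal(oursc$df, unname(refc$parameter))
      expect_equal(oursc$p_value, refc$p.value, tolerance = 1e-8)
    }
  })
})

test_that("t-test degenerate inputs and antisymmetry behave", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(two_sample_t(x, x)$statistic, 0)
  expect_equal(two_sample_t(x, x)$p_value, 1)
  expect_equal(two_sample_t(x, c(2, 3, 4, 5, 6))$statistic,
               -two_sample_t(c(2, 3, 4, 5, 6), x)$statistic)
  expect_equal(two_sample_t(rep(1, 3), rep(1, 4))$p_value, 1)
  expect_error(two_sample_t(rep(1, 3), rep(2, 4)), "zero variance")
  expect_error(two_sample_t(1, x), "n >= 2")
})

test_that("Cohen's d is affine-invariant and consistent", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(a + 7, b + 7), cohens_d(a, b))
  expect_equal(cohens_d(a * 3, b * 3), cohens_d(a, b))
  withr::with_seed(13, {
    big_a <- rnorm(10000, 0.8, 1)
    big_b <- rnorm(10000, 0, 1)
  })
  expect_lt(abs(cohens_d(big_a, big_b) - 0.8), 0.05)
})

test_that("BH step-up reproduces the hand-worked example and its properties", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up by hand: adj_(i) = min_{j >= i} (m/j) p_(j), capped at 1
  m <- length(p)
  expected <- rev(cummin(rev(p * m / seq_len(m))))
  expected <- pmin(expected, 1)
  res <- bh_fdr(p, q = 0.05)
  expect_equal(res$p_adjusted, expected, tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p))
  expect_identical(res$significant, res$p_adjusted < 0.05)
  expect_false(any(bh_fdr(rep(1, 6))$significant))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("chi-square df and degenerate tables", {
  lab <- rep(1:2, each = 35)
  site <- rep(sprintf("s%d", 1:7), 10)
  expect_equal(chi_square_site_composition(lab, site)$df, 6)
  # proportional rows give exactly zero
  lab0 <- rep(1:2, times = 20)
  site0 <- rep(c("a", "a", "b", "b"), 10)
  expect_equal(chi_square_site_composition(lab0, site0)$statistic, 0)
  # frozen 2x2 closed form: rows (10,20)/(20,10) -> chi2 = 20/3
  lab22 <- rep(1:2, each = 30)
  site22 <- c(rep("a", 10), rep("b", 20), rep("a", 20), rep("b", 10))
  expect_equal(chi_square_site_composition(lab22, site22)$statistic, 20 / 3,
               tolerance = 1e-12)
})

test_that("Pearson r edge behavior", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  y <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  expect_equal(pearson_r(x, y)$estimate, pearson_r(y, x)$estimate)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(c(1, 2, NA), c(NA, 1, 2)), "3 complete")
})

test_that("effect maps flag planted opposite-direction subtypes", {
  co <- small_cohort(seed = 17, n_hc = 80, n_asd = 80, d = 1.2)
  truth <- co$true_subtype[co$diagnosis == "patient"]
  labels <- setNames(truth, co$subject_id[co$diagnosis == "patient"])
  maps <- polysub:::effect_map_by_subtype(co, labels)
  aff <- attr(co, "affected_features")
  d1 <- maps$subtype1$cohens_d[maps$subtype1$feature %in% aff]
  d2 <- maps$subtype2$cohens_d[maps$subtype2$feature %in% aff]
  expect_gt(median(d1), 0)
  expect_lt(median(d2), 0)
  # mask <-> adjusted p agreement
  for (mthis in maps) {
    expect_identical(mthis$significant, mthis$p_adjusted < 0.05)
  }
})

test_that("subtype report compares groups and tolerates absent scores", {
  co <- small_cohort(seed = 19, n_hc = 80, n_asd = 80, d = 1)
  truth <- co$true_subtype[co$diagnosis == "patient"]
  labels <- setNames(truth, co$subject_id[co$diagnosis == "patient"])
  co$ados_total[!is.na(co$true_subtype) & co$true_subtype == 2] <- NA
  rep <- subtype_report(co, labels)
  row <- rep$clinical[rep$clinical$variable == "ados_total", ]
  expect_true(grepl("subtype2", row$absent_in))
  expect_true(is.na(row$p_s1_s2))
  expect_equal(rep$site_composition$df,
               (2 - 1) * (length(unique(co$site)) - 1))
  expect_true(all(rep$tiv_correlations$r >= -1 &
                    rep$tiv_correlations$r <= 1, na.rm = TRUE))
})

test_that("configured FIQ subtype difference is detected at the analytic power", {
  # at the configured clinical means (111 +- 15.3 vs 104 +- 13.5, ~110 per
  # subtype) the analytic power at alpha = 0.01 is the oracle expectation
  n_rep <- 40
  hits <- sapply(seq_len(n_rep), function(s) {
    co <- simulate_cohort(n_hc = 20, n_asd = 220, n_features = 5,
                          seed = 600 + s)
    g1 <- co$fiq[co$diagnosis == "patient" & co$true_subtype == 1]
    g2 <- co$fiq[co$diagnosis == "patient" & co$true_subtype == 2]
    two_sample_t(g1, g2)$p_value < 0.01
  })
  pow <- stats::power.t.test(n = 110, delta = 111 - 104,
                             sd = sqrt((15.3^2 + 13.5^2) / 2),
                             sig.level = 0.01)$power
  expect_lt(abs(mean(hits) - pow),
            3 * sqrt(pow * (1 - pow) / n_rep) + 0.02)
})
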