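test_that("balanced repeats equalize class sizes without replacement", {
  y <- c(rep("control", 257), rep("patient", 115))
  reps <- balanced_repeats(y, n_repeats = 10, seed = 4)
  for (idx in reps) {
    expect_equal(sum(y[idx] == "control"), 115)
    expect_equal(sum(y[idx] == "patient"), 115)
    expect_equal(anyDuplicated(idx), 0)
  }
  # at least two distinct control subsets across repeats
  expect_gt(length(unique(vapply(reps, paste, character(1),
                                 collapse = ","))), 1)
  # equal sizes: subsample is the full majority class every time
  y_eq <- rep(c("a", "b"), each = 20)
  reps_eq <- balanced_repeats(y_eq, n_repeats = 3, seed = 1)
  expect_true(all(vapply(reps_eq, length, integer(1)) == 40))
  expect_equal(length(unique(reps_eq)), 1)
})

test_that("nested CV is perfect on separable data and chance on permuted labels", {
  withr::with_seed(61, {
    X <- rbind(matrix(rnorm(40 * 5), 40, 5),
               matrix(rnorm(40 * 5, mean = 6), 40, 5))
    y <- rep(c("a", "b"), each = 40)
  })
  res <- nested_cv_svm(X, y, outer_folds = 5, inner_folds = 3,
                       c_grid = c(0.1, 1), seed = 2)
  expect_equal(res$accuracy_pct, 100)
  # bookkeeping oracle: reported accuracy equals the stored predictions
  expect_equal(mean(res$predictions == res$truth) * 100,
               mean(res$fold_accuracy))

  withr::with_seed(62, {
    Xn <- matrix(rnorm(100 * 10), 100, 10)
    yn <- sample(rep(c("a", "b"), each = 50))
  })
  resn <- nested_cv_svm(Xn, yn, outer_folds = 5, inner_folds = 3,
                        c_grid = c(0.1, 1), seed = 3)
  expect_lt(abs(resn$accuracy_pct - 50), 20)

  # determinism under a fixed seed
  res2 <- nested_cv_svm(X, y, outer_folds = 5, inner_folds = 3,
                        c_grid = c(0.1, 1), seed = 2)
  expect_identical(res$fold_accuracy, res2$fold_accuracy)
})

test_that("the dual-CD linear SVC agrees with an independent library", {
  # libsvm (unregularized bias) vs our augmented-bias formulation: on
  # centered data (the pipeline standardizes within folds) the optimal bias
  # is near zero and the two formulations coincide
  withr::with_seed(64, {
    Xtr <- rbind(matrix(rnorm(30 * 8, mean = -0.6), 30, 8),
                 matrix(rnorm(30 * 8, mean = 0.6), 30, 8))
    ytr <- rep(c("a", "b"), each = 30)
    Xte <- rbind(matrix(rnorm(50 * 8, mean = -0.6), 50, 8),
                 matrix(rnorm(50 * 8, mean = 0.6), 50, 8))
    yte <- rep(c("a", "b"), each = 50)
  })
  for (C in c(0.1, 1, 10)) {
    ours <- polysub:::linear_svc(Xtr, ytr, C = C, tol = 1e-4)
    ref <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = C,
                      scale = FALSE)
    acc_ours <- mean(predict(ours, Xte) == yte)
    acc_ref <- mean(predict(ref, Xte) == yte)
    expect_lt(abs(acc_ours - acc_ref), 0.05)
    # weight directions align
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    w_ref <- w_ref * sign(sum(ours$w * w_ref))
    expect_gt(cor(ours$w, w_ref), 0.98)
  }
})

test_that("weights concentrate on the informative feature", {
  withr::with_seed(63, {
    x1 <- c(rnorm(40), rnorm(40, 4))
    x2 <- rnorm(80)
    y <- rep(c("a", "b"), each = 40)
  })
  res <- nested_cv_svm(cbind(x1, x2), y, outer_folds = 5, inner_folds = 3,
                       c_grid = c(0.1, 1), seed = 5)
  expect_gt(res$mean_abs_weight[1], res$mean_abs_weight[2])
})

test_that("subtype-aware evaluation shows gains only under heterogeneity", {
  # opposite planted effects: subtype classifiers beat the pooled one
  co <- simulate_cohort(n_hc = 60, n_asd = 60, n_sites = 2, n_features = 20,
                        effect_size_d = 1.2, seed = 71)
  res <- residualize(co, fit_covariate_model(co))
  truth <- co$true_subtype[co$diagnosis == "patient"]
  labels <- setNames(truth, co$subject_id[co$diagnosis == "patient"])
  ev <- subtype_aware_evaluation(res, labels, n_repeats = 2,
                                 outer_folds = 4, inner_folds = 3,
                                 c_grid = c(0.1, 1), seed = 5)
  expect_gte(min(ev$gains), 10)
  expect_equal(ev$subtype1$n_per_class, sum(truth == 1))

  # the two subtype tasks disagree on feature importance more than one task
  # re-estimated with fresh balancing/folds disagrees with itself
  ids1 <- names(labels)[labels == 1]
  rows1 <- c(which(res$diagnosis == "control"),
             match(ids1, res$subject_id))
  X1 <- polysub:::feature_matrix(res)[rows1, ]
  y1 <- res$diagnosis[rows1]
  rerun <- lapply(c(11, 12), function(s) {
    svm_accuracy_report(X1, y1, n_repeats = 2, outer_folds = 4,
                        inner_folds = 3, c_grid = c(0.1, 1), seed = s)
  })
  wrc_same <- cor(rerun[[1]]$weights$rank, rerun[[2]]$weights$rank,
                  method = "spearman")
  expect_lt(ev$weight_rank_correlation, wrc_same)

  # single planted direction: splitting the patients in half buys nothing
  co1 <- simulate_cohort(n_hc = 60, n_asd = 60, n_sites = 2, n_features = 20,
                         effect_size_d = 1.2, subtype_fractions = 1,
                         seed = 72)
  res1 <- residualize(co1, fit_covariate_model(co1))
  pat_ids <- co1$subject_id[co1$diagnosis == "patient"]
  labels1 <- setNames(rep_len(1:2, length(pat_ids)), pat_ids)
  ev1 <- subtype_aware_evaluation(res1, labels1, n_repeats = 2,
                                  outer_folds = 4, inner_folds = 3,
                                  c_grid = c(0.1, 1), seed = 6)
  expect_lte(max(abs(ev1$gains)), 5)
})
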