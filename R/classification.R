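# Balanced, repeated, nested cross-validated linear SVM classification
# between (sub)groups, with per-feature weight ranking.

#' Balanced subsampling repeats
#'
#' Subsamples the majority class without replacement down to the minority
#' size, once per repeat.
#'
#' @param y class labels (two classes).
#' @param n_repeats number of balancing repeats.
#' @param seed integer seed.
#' @return list of index vectors into `y` (each balanced).
#' @export
balanced_repeats <- function(y, n_repeats = 10, seed = 1L) {
  classes <- unique(y)
  if (length(classes) != 2) abort("exactly two classes required")
  i1 <- which(y == classes[1])
  i2 <- which(y == classes[2])
  if (length(i1) == 0 || length(i2) == 0) abort("a class is empty")
  if (length(i1) > length(i2)) {
    maj <- i1
    mnr <- i2
  } else {
    maj <- i2
    mnr <- i1
  }
  lapply(seq_len(n_repeats), function(r) {
    sub <- with_seed(child_seed(seed, "balance", r),
                     sample(maj, length(mnr)))
    sort(c(mnr, sub))
  })
}

# Linear C-SVM used by the classification tasks: L1-loss dual coordinate
# descent with the bias as an augmented constant feature (compiled).
# Validated against libsvm in the test suite.
linear_svc <- function(X, y, C, tol = 0.01, max_epochs = 200, seed = 1L) {
  lev <- levels(factor(y))
  yy <- ifelse(as.character(y) == lev[1], 1, -1)
  Xa <- cbind(X, 1)
  fit <- linear_svc_cd(Xa, yy, C, tol = tol, max_epochs = max_epochs,
                       seed = as.integer(seed))
  structure(list(w = fit$w[seq_len(ncol(X))], b = fit$w[ncol(X) + 1],
                 levels = lev, epochs = fit$epochs),
            class = "polysub_svc")
}

#' @export
predict.polysub_svc <- function(object, newx, ...) {
  score <- drop(as.matrix(newx) %*% object$w) + object$b
  factor(ifelse(score >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

# fold-local standardization learned on training rows only
fold_scale <- function(X, train) {
  Xt <- X[train, , drop = FALSE]
  n <- nrow(Xt)
  ctr <- colMeans(Xt)
  scl <- sqrt(pmax(colSums(Xt^2) / n - ctr^2, 0) * n / (n - 1))
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, "/"))
}

#' Nested cross-validated linear SVM
#'
#' Stratified outer folds; within every outer training set, the cost C is
#' chosen from `c_grid` by inner cross-validated accuracy (ties to the
#' smallest C), the model is refitted and scored on the outer test fold.
#' Standardization is learned inside each training fold only; no feature
#' selection is performed. Absolute linear weights are averaged over the
#' outer refits.
#'
#' @param x feature matrix.
#' @param y two-class labels.
#' @param outer_folds,inner_folds fold counts.
#' @param c_grid candidate SVM cost values.
#' @param seed integer seed.
#' @return list: `accuracy_pct` (mean outer-fold accuracy, percent),
#'   `fold_accuracy`, `predictions` (per subject), `mean_abs_weight`,
#'   `chosen_c`.
#' @export
nested_cv_svm <- function(x, y, outer_folds = 10, inner_folds = 10,
                          c_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) abort("exactly two classes required")
  folds <- stratified_folds(as.character(y), outer_folds,
                            child_seed(seed, "outer"))
  fold_acc <- numeric(outer_folds)
  chosen_c <- numeric(outer_folds)
  wsum <- numeric(ncol(x))
  preds <- rep(NA_character_, length(y))
  for (f in seq_len(outer_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2 || length(te) == 0) {
      abort("degenerate outer fold")
    }
    sc <- fold_scale(x, tr)
    x_tr <- x[tr, , drop = FALSE]
    y_tr <- y[tr]
    Xtr <- sc$apply(x_tr)
    # inner CV to choose C on training data only
    inner <- stratified_folds(as.character(y_tr), inner_folds,
                              child_seed(seed, "inner", f))
    inner_sets <- lapply(seq_len(inner_folds), function(g) {
      itr <- which(inner != g)
      ite <- which(inner == g)
      if (length(unique(y_tr[itr])) < 2 || length(ite) == 0) return(NULL)
      isc <- fold_scale(x_tr, itr)
      list(Xi = isc$apply(x_tr[itr, , drop = FALSE]),
           Xo = isc$apply(x_tr[ite, , drop = FALSE]),
           yi = y_tr[itr], yo = y_tr[ite])
    })
    inner_acc <- vapply(c_grid, function(C) {
      mean(vapply(inner_sets, function(set) {
        if (is.null(set)) return(NA_real_)
        # truncated solves suffice for model selection
        m <- linear_svc(set$Xi, set$yi, C = C, tol = 0.05, max_epochs = 60)
        mean(predict(m, set$Xo) == set$yo)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    C_best <- c_grid[which.max(inner_acc)]   # ties -> smallest C
    chosen_c[f] <- C_best
    m <- linear_svc(Xtr, y_tr, C = C_best, tol = 0.001, max_epochs = 500)
    pred <- predict(m, sc$apply(x[te, , drop = FALSE]))
    preds[te] <- as.character(pred)
    fold_acc[f] <- mean(pred == y[te])
    wsum <- wsum + abs(m$w)
  }
  list(accuracy_pct = mean(fold_acc) * 100,
       fold_accuracy = fold_acc * 100,
       predictions = preds,
       truth = as.character(y),
       mean_abs_weight = wsum / outer_folds,
       chosen_c = chosen_c)
}

#' Balanced repeated nested-CV accuracy report
#'
#' Repeats class balancing `n_repeats` times and runs [nested_cv_svm()] on
#' every balanced subset; accuracy is the mean over repeats (in percent, as
#' conventionally reported), and the per-feature importance is the mean
#' absolute linear weight with its rank.
#'
#' @param x feature matrix.
#' @param y two-class labels.
#' @param n_repeats balancing repeats.
#' @param outer_folds,inner_folds,c_grid see [nested_cv_svm()].
#' @param seed integer seed.
#' @return A `polysub_accuracy`: `accuracy_pct`, `per_repeat`, `weights`
#'   tibble (feature, mean |w|, rank), sizes, seed.
#' @export
svm_accuracy_report <- function(x, y, n_repeats = 10, outer_folds = 10,
                                inner_folds = 10,
                                c_grid = c(0.01, 0.1, 1, 10, 100),
                                seed = 1L) {
  x <- as.matrix(x)
  reps <- balanced_repeats(y, n_repeats = n_repeats,
                           seed = child_seed(seed, "reps"))
  res <- lapply(seq_along(reps), function(r) {
    idx <- reps[[r]]
    nested_cv_svm(x[idx, , drop = FALSE], y[idx],
                  outer_folds = outer_folds, inner_folds = inner_folds,
                  c_grid = c_grid, seed = child_seed(seed, "cv", r))
  })
  acc <- vapply(res, `[[`, numeric(1), "accuracy_pct")
  w <- rowMeans(vapply(res, `[[`, numeric(ncol(x)), "mean_abs_weight"))
  nm <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(
    list(accuracy_pct = mean(acc),
         per_repeat = acc,
         weights = tibble::tibble(feature = nm, mean_abs_weight = w,
                                  rank = rank(-w, ties.method = "min")),
         n_per_class = min(table(y)),
         n_repeats = n_repeats, seed = seed,
         runs = res),
    class = "polysub_accuracy"
  )
}

#' @export
print.polysub_accuracy <- function(x, ...) {
  cat("<polysub_accuracy> mean accuracy ",
      sprintf("%.2f%%", x$accuracy_pct), " over ", x$n_repeats,
      " balanced repeats (n = ", x$n_per_class, " per class)\n", sep = "")
  invisible(x)
}

#' @export
tidy.polysub_accuracy <- function(x, ...) {
  dplyr::arrange(x$weights, .data$rank)
}

#' @export
glance.polysub_accuracy <- function(x, ...) {
  tibble::tibble(accuracy_pct = x$accuracy_pct,
                 sd_pct = sd(x$per_repeat),
                 n_repeats = x$n_repeats,
                 n_per_class = x$n_per_class)
}

#' Subtype-aware classification evaluation
#'
#' Runs the balanced repeated nested-CV linear SVM for (a) all patients vs
#' controls, (b) each subtype vs controls, on the table's (typically
#' residualized) features, and reports the accuracy gains of the
#' subtype-specific classifiers over the pooled one plus the Spearman
#' correlation of the two subtype weight rankings.
#'
#' @param data subject table.
#' @param labels named integer consensus labels for patients.
#' @param n_repeats,outer_folds,inner_folds,c_grid see
#'   [svm_accuracy_report()].
#' @param seed integer seed.
#' @return list: `all_patients`, `subtype1`, `subtype2`
#'   (`polysub_accuracy` each), `gains` (percentage points), and
#'   `weight_rank_correlation` between the subtype tasks.
#' @export
subtype_aware_evaluation <- function(data, labels, n_repeats = 10,
                                     outer_folds = 10, inner_folds = 10,
                                     c_grid = c(0.01, 0.1, 1, 10, 100),
                                     seed = 1L) {
  X <- feature_matrix(data)
  ctrl <- which(data$diagnosis == "control")
  pat <- which(data$diagnosis == "patient")
  ks <- sort(unique(as.integer(labels)))
  task <- function(idx_pos, s) {
    rows <- c(ctrl, idx_pos)
    svm_accuracy_report(X[rows, , drop = FALSE],
                        c(rep("control", length(ctrl)),
                          rep("patient", length(idx_pos))),
                        n_repeats = n_repeats, outer_folds = outer_folds,
                        inner_folds = inner_folds, c_grid = c_grid,
                        seed = child_seed(seed, "task", s))
  }
  all_rep <- task(pat, 0L)
  sub_reps <- lapply(ks, function(j) {
    ids <- names(labels)[labels == j]
    task(match(ids, data$subject_id), j)
  })
  names(sub_reps) <- paste0("subtype", ks)
  gains <- vapply(sub_reps, function(r) {
    r$accuracy_pct - all_rep$accuracy_pct
  }, numeric(1))
  wrc <- if (length(sub_reps) >= 2) {
    cor(sub_reps[[1]]$weights$rank, sub_reps[[2]]$weights$rank,
        method = "spearman")
  } else {
    NA_real_
  }
  c(list(all_patients = all_rep), sub_reps,
    list(gains = gains, weight_rank_correlation = wrc))
}

#' @export
autoplot.polysub_accuracy <- function(object, ...) {
  df <- tibble::tibble(repeat_id = seq_along(object$per_repeat),
                       accuracy_pct = object$per_repeat)
  ggplot2::ggplot(df, ggplot2::aes(.data$repeat_id, .data$accuracy_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$accuracy_pct, linetype = 2) +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::scale_x_continuous(breaks = df$repeat_id) +
    ggplot2::labs(x = "balancing repeat", y = "accuracy (%)",
                  title = "Balanced nested-CV accuracy per repeat") +
    ggplot2::theme_minimal()
}
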