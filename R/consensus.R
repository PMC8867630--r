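#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the contingency table of the two
#' labelings:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{M - E}, \quad
#'   E = \frac{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2}}{\binom{n}{2}},
#'   \quad M = \tfrac12\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right]}
#' Pairs where either labeling is missing are dropped.
#'
#' @param labels_a,labels_b equal-length label vectors (NA allowed).
#' @return scalar in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("labelings differ in length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]
  b <- labels_b[keep]
  n <- length(a)
  if (n < 2) abort("fewer than 2 items labeled in both partitions")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  e <- sum_a * sum_b / ch2(n)
  m <- (sum_a + sum_b) / 2
  if (m == e) return(1)     # both partitions trivial (all one cluster / all singletons agree)
  (sum_ij - e) / (m - e)
}

#' Cross-validated clustering label runs
#'
#' Stratified k-fold cross-validation of the polytope fit: for every fold,
#' the model is fitted on the other folds' subjects and the training
#' patients' face labels are recorded. Each patient therefore accrues
#' `folds - 1` labels (it is absent from exactly one training set).
#'
#' @param data subject table (typically residualized features).
#' @param k number of subtypes.
#' @param folds number of cross-validation folds; stratified by diagnosis
#'   and site so every training set contains every site.
#' @param seed integer seed (fold composition and fit initializations).
#' @param ... passed to [fit_polytope()].
#' @return A `polysub_label_runs`: patients x folds integer matrix (NA where
#'   the patient was held out), with the patient ids and fold assignment.
#' @export
cross_validated_clustering <- function(data, k, folds = 10, seed = 1L, ...) {
  if (folds < 2) abort("folds must be >= 2")
  strata <- paste(data$diagnosis, data$site)
  fold_id <- stratified_folds(strata, folds, child_seed(seed, "folds"))
  pat <- which(data$diagnosis == "patient")
  runs <- matrix(NA_integer_, length(pat), folds,
                 dimnames = list(data$subject_id[pat], NULL))
  for (f in seq_len(folds)) {
    train <- which(fold_id != f)
    if (length(unique(data$diagnosis[train])) < 2) {
      abort("a training fold lost one diagnosis class")
    }
    fit <- fit_polytope(data[train, ], k = k,
                        seed = child_seed(seed, "fit", f), ...)
    train_pat <- train[data$diagnosis[train] == "patient"]
    runs[match(train_pat, pat), f] <- fit$labels
  }
  structure(list(labels = runs, k = k, folds = folds, fold_id = fold_id,
                 patient_ids = data$subject_id[pat], seed = seed),
            class = "polysub_label_runs")
}

#' @export
print.polysub_label_runs <- function(x, ...) {
  cat("<polysub_label_runs> ", nrow(x$labels), " patients x ", x$folds,
      " folds, k = ", x$k, "\n", sep = "")
  invisible(x)
}

# mean pairwise ARI across fold labelings, restricted to shared patients
mean_pairwise_ari <- function(runs) {
  L <- runs$labels
  pairs <- combn(ncol(L), 2)
  mean(apply(pairs, 2, function(p) adjusted_rand_index(L[, p[1]], L[, p[2]])))
}

# co-occurrence matrix A_uv = (# runs where u,v share a label) /
#                             (# runs where both are labeled)
co_occurrence <- function(runs) {
  L <- runs$labels
  n <- nrow(L)
  obs <- !is.na(L)
  both <- tcrossprod(obs * 1)                 # runs where both labeled
  same <- matrix(0, n, n)
  for (f in seq_len(ncol(L))) {
    lab <- L[, f]
    ok <- which(!is.na(lab))
    s <- outer(lab[ok], lab[ok], "==") * 1
    same[ok, ok] <- same[ok, ok] + s
  }
  A <- same / both
  never <- both == 0 & row(both) != col(both)
  if (any(never)) {
    warn(paste0(sum(never) / 2, " patient pair(s) never co-observed; ",
                "using the overall mean co-occurrence"))
    A[never] <- mean(A[upper.tri(A) & !never], na.rm = TRUE)
  }
  diag(A) <- 1
  dimnames(A) <- list(rownames(L), rownames(L))
  A
}

#' Consensus labels from cross-validated label runs
#'
#' Builds the patient co-occurrence matrix over runs and partitions it
#' spectrally: k-means (restarted `consensus_steps` times with different
#' seeded starts) on the top-k eigenvectors of the normalized co-occurrence.
#' The partition with the highest mean within-cluster co-occurrence wins.
#'
#' @param runs a `polysub_label_runs`.
#' @param k number of consensus clusters (defaults to the runs' k).
#' @param consensus_steps seeded partitioner repetitions.
#' @param seed integer seed.
#' @return integer consensus labels (named by patient id) with the
#'   co-occurrence matrix in attribute `co_occurrence`.
#' @export
consensus_labels <- function(runs, k = NULL, consensus_steps = 20, seed = 1L) {
  k <- k %||% runs$k
  A <- co_occurrence(runs)
  n <- nrow(A)
  if (k >= n) abort("k must be smaller than the number of patients")
  # normalized spectral embedding
  dinv <- 1 / sqrt(rowSums(A))
  Ln <- A * tcrossprod(dinv)
  eig <- eigen(Ln, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)

  score <- function(lab) {
    mean(vapply(unique(lab), function(cl) {
      i <- which(lab == cl)
      if (length(i) == 1) return(1)
      mean(A[i, i][upper.tri(A[i, i])])
    }, numeric(1)))
  }
  best <- NULL
  best_score <- -Inf
  for (s in seq_len(consensus_steps)) {
    km <- suppressWarnings(
      with_seed(child_seed(seed, "consensus", s),
                kmeans(U, centers = k, nstart = 1, iter.max = 100,
                       algorithm = "Lloyd")))
    sc <- score(km$cluster)
    if (sc > best_score) {
      best_score <- sc
      best <- km$cluster
    }
  }
  out <- setNames(canonical_labels(best), rownames(A))
  attr(out, "co_occurrence") <- A
  attr(out, "within_co_occurrence") <- best_score
  out
}

#' Cross-validated stability sweep over candidate subtype counts
#'
#' For every k in `k_range`, runs [cross_validated_clustering()], scores
#' stability as the mean pairwise adjusted Rand index across fold labelings
#' (restricted to shared patients), and computes consensus labels. The
#' selected k maximizes mean ARI; ties resolve to the smallest k.
#'
#' @param data subject table (typically residualized).
#' @param k_range candidate subtype counts.
#' @param folds cross-validation folds.
#' @param consensus_steps consensus partitioner repetitions per k.
#' @param seed integer seed.
#' @param ... passed to [fit_polytope()].
#' @return A `polysub_stability`: tibble of k vs mean ARI, consensus labels
#'   per k, `selected_k`.
#' @export
stability_sweep <- function(data, k_range = 2:8, folds = 10,
                            consensus_steps = 20, seed = 1L, ...) {
  fold_id <- stratified_folds(paste(data$diagnosis, data$site), folds,
                              child_seed(seed, "folds"))
  pat_per_fold <- tabulate(fold_id[data$diagnosis == "patient"], folds)
  min_train_patients <- sum(data$diagnosis == "patient") - max(pat_per_fold)
  if (max(k_range) > min_train_patients) {
    abort("max(k_range) exceeds the patient count of the smallest training fold")
  }
  res <- purrr::map(k_range, function(k) {
    runs <- cross_validated_clustering(data, k, folds = folds, seed = seed, ...)
    list(k = k, ari = mean_pairwise_ari(runs),
         consensus = consensus_labels(runs, k,
                                      consensus_steps = consensus_steps,
                                      seed = child_seed(seed, "cons", k)),
         runs = runs)
  })
  ari <- vapply(res, `[[`, numeric(1), "ari")
  profile <- tibble::tibble(k = as.integer(k_range), mean_ari = ari)
  structure(
    list(profile = profile,
         selected_k = as.integer(k_range[which.max(ari)]),  # ties -> smallest
         consensus = setNames(lapply(res, `[[`, "consensus"),
                              paste0("k", k_range)),
         runs = setNames(lapply(res, `[[`, "runs"), paste0("k", k_range)),
         folds = folds, k_range = as.integer(k_range),
         consensus_steps = consensus_steps, seed = seed),
    class = "polysub_stability"
  )
}

#' Consensus subtype labels at the selected (or given) k
#'
#' @param profile a `polysub_stability`.
#' @param k subtype count (default: the selected k).
#' @return named integer vector of patient subtype labels.
#' @export
subtype_labels <- function(profile, k = NULL) {
  k <- k %||% profile$selected_k
  lab <- profile$consensus[[paste0("k", k)]]
  if (is.null(lab)) abort("k not in the sweep range")
  lab
}

#' @export
print.polysub_stability <- function(x, ...) {
  cat("<polysub_stability> k range ", min(x$k_range), "..", max(x$k_range),
      ", selected k = ", x$selected_k, "\n", sep = "")
  print(x$profile, n = Inf)
  invisible(x)
}

#' @export
tidy.polysub_stability <- function(x, ...) {
  x$profile
}

#' @export
glance.polysub_stability <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 max_mean_ari = max(x$profile$mean_ari),
                 folds = x$folds, n_k = nrow(x$profile))
}

#' @export
autoplot.polysub_stability <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$k, .data$mean_ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = object$profile$k) +
    ggplot2::labs(x = "number of subtypes (k)",
                  y = "mean cross-validated ARI",
                  title = "Clustering stability by subtype count") +
    ggplot2::theme_minimal()
}

#' Write a stability profile (and consensus labels) to disk
#'
#' `stability.json` holds the ARI profile and selected k; one CSV per k holds
#' the consensus labels; the co-occurrence matrix of the selected k is
#' written as CSV.
#'
#' @param profile a `polysub_stability`.
#' @param dir output directory.
#' @export
write_stability <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(profile = profile$profile, selected_k = profile$selected_k,
         folds = profile$folds, seed = profile$seed),
    file.path(dir, "stability.json"), digits = NA, auto_unbox = TRUE)
  for (k in profile$k_range) {
    lab <- profile$consensus[[paste0("k", k)]]
    write.csv(data.frame(subject_id = names(lab), subtype = as.integer(lab)),
              file.path(dir, sprintf("consensus_k%d.csv", k)),
              row.names = FALSE)
  }
  A <- attr(profile$consensus[[paste0("k", profile$selected_k)]],
            "co_occurrence")
  write.csv(as.data.frame(A),
            file.path(dir, "co_occurrence_selected_k.csv"))
  invisible(dir)
}
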