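# Sliding-window dynamic measures on parcel time series: ReHo, DC, GSCorr,
# VMHC per window, their temporal SD maps, volume-wise Kendall-W concordance
# across the four measures, and dynamic functional-architecture stability.

#' Exclude subjects by head motion
#'
#' Retains subjects whose maximum translation and rotation are both at or
#' below the thresholds. Subjects with missing motion metadata are excluded
#' with a warning.
#'
#' @param data subject table with `max_translation_mm`, `max_rotation_deg`.
#' @param max_translation_mm,max_rotation_deg exclusion thresholds (strictly
#'   greater excludes).
#' @return the retained rows; attribute `exclusion_log` tabulates the
#'   reasons.
#' @export
motion_filter <- function(data, max_translation_mm = 2.0,
                          max_rotation_deg = 2.0) {
  if (nrow(data) == 0) {
    return(structure(data, exclusion_log = tibble::tibble(
      reason = character(0), n = integer(0))))
  }
  tr <- data$max_translation_mm
  ro <- data$max_rotation_deg
  missing <- is.na(tr) | is.na(ro)
  if (any(missing)) {
    warn(paste0(sum(missing), " subject(s) lack motion metadata; excluded"))
  }
  excess <- !missing & (tr > max_translation_mm | ro > max_rotation_deg)
  keep <- !missing & !excess
  log <- tibble::tibble(
    reason = c("missing_motion_metadata", "excess_motion", "retained"),
    n = c(sum(missing), sum(excess), sum(keep))
  )
  structure(data[keep, ], exclusion_log = log)
}

#' Sliding-window index ranges
#'
#' Windows are `[1 + k*step, k*step + length]`, fully inside the series.
#'
#' @param n_timepoints series length T.
#' @param length,step window length and step, in timepoints.
#' @return list of integer index vectors (`floor((T - length)/step) + 1` of
#'   them).
#' @export
make_windows <- function(n_timepoints, length = 30, step = 5) {
  if (length < 2 || length > n_timepoints) {
    abort("window length must be in [2, n_timepoints]")
  }
  if (step < 1) abort("step must be >= 1")
  starts <- seq(1, n_timepoints - length + 1, by = step)
  lapply(starts, function(s) seq(s, s + length - 1))
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m raters ranking n items, with mid-rank ties and the tie
#' correction:
#' \deqn{W = \frac{12 \sum_i (R_i - m(n+1)/2)^2}{m^2(n^3 - n) - m T}, \quad
#'       T = \sum_{raters} \sum_{ties} (t^3 - t)}
#' Raw scores are ranked internally. On untied data with m raters, W equals
#' \eqn{((m-1)\bar\rho + 1)/m} for the mean pairwise Spearman correlation
#' \eqn{\bar\rho}; the null expectation is 1/m.
#'
#' @param scores m x n matrix (rows = raters, columns = items).
#' @return scalar W in \[0, 1\].
#' @export
kendalls_w <- function(scores) {
  scores <- as.matrix(scores)
  m <- nrow(scores)
  n <- ncol(scores)
  if (m < 2 || n < 2) abort("need >= 2 raters and >= 2 items")
  ranks <- t(apply(scores, 1, rank))
  if (all(apply(ranks, 1, function(r) length(unique(r)) == 1))) {
    abort("every rater ties all items; W undefined")
  }
  R <- colSums(ranks)
  tie_term <- sum(apply(scores, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  }))
  num <- 12 * sum((R - m * (n + 1) / 2)^2)
  den <- m^2 * (n^3 - n) - m * tie_term
  num / den
}

#' Windowed dynamic measures of one subject's parcel series
#'
#' Per sliding window: ReHo (Kendall's W of each parcel with its neighbor
#' set), DC (count of other parcels with window Pearson r above
#' `dc_threshold`), GSCorr (Pearson r with the all-parcel mean course) and
#' VMHC (Pearson r of homotopic-pair courses, assigned to both parcels;
#' missing for unpaired parcels). Neighbor sets default to the
#' `reho_k` nearest parcels by full-series correlation.
#'
#' @param series a `polysub_series` (or list with `mat`, `homotopic_pairs`).
#' @param window_length,window_step window specification in timepoints.
#' @param dc_threshold correlation threshold for degree centrality.
#' @param reho_k neighbors per parcel for ReHo.
#' @param adjacency optional logical/0-1 parcel x parcel neighbor matrix
#'   overriding the correlation-based neighborhoods.
#' @return A `polysub_dynmaps`: list of four parcels x windows matrices
#'   (`reho`, `dc`, `gscorr`, `vmhc`) sharing one window grid.
#' @export
windowed_measures <- function(series, window_length = 30, window_step = 5,
                              dc_threshold = 0.25, reho_k = 6,
                              adjacency = NULL) {
  mat <- series$mat
  p <- nrow(mat)
  if (p < 3) abort("need >= 3 parcels")
  if (window_length < 3) abort("window shorter than 3 timepoints")
  windows <- make_windows(ncol(mat), window_length, window_step)
  nw <- length(windows)

  if (is.null(adjacency)) {
    full_cor <- cor(t(mat))
    diag(full_cor) <- -Inf
    neighbors <- lapply(seq_len(p), function(i) {
      order(full_cor[i, ], decreasing = TRUE)[seq_len(min(reho_k, p - 1))]
    })
  } else {
    neighbors <- lapply(seq_len(p), function(i) which(adjacency[i, ] > 0 &
                                                        seq_len(p) != i))
  }

  pairs <- series$homotopic_pairs
  pair_of <- rep(NA_integer_, p)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pair_of[pairs[, 1]] <- pairs[, 2]
    pair_of[pairs[, 2]] <- pairs[, 1]
  }

  reho <- dc <- gscorr <- vmhc <- matrix(NA_real_, p, nw,
                                         dimnames = list(rownames(mat), NULL))
  for (w in seq_len(nw)) {
    X <- mat[, windows[[w]], drop = FALSE]       # parcels x length
    len <- ncol(X)
    cw <- cor(t(X))
    gs <- colMeans(X)
    dc[, w] <- rowSums(cw > dc_threshold, na.rm = TRUE) -
      (diag(cw) > dc_threshold)
    gscorr[, w] <- suppressWarnings(as.vector(cor(t(X), gs)))
    # ReHo: Kendall's W of each parcel with its neighbor set. Ranks and
    # per-parcel tie terms are computed once per window; W for a parcel set
    # then needs only the column sums of its rank rows.
    ranks <- t(apply(X, 1, rank))
    tie_term <- apply(X, 1, function(x) {
      if (anyDuplicated(x) == 0) return(0)
      tt <- tabulate(match(x, unique(x)))
      sum(tt^3 - tt)
    })
    for (i in seq_len(p)) {
      set <- c(i, neighbors[[i]])
      m <- length(set)
      R <- colSums(ranks[set, , drop = FALSE])
      num <- 12 * sum((R - m * (len + 1) / 2)^2)
      den <- m^2 * (len^3 - len) - m * sum(tie_term[set])
      reho[i, w] <- num / den
      if (!is.na(pair_of[i])) vmhc[i, w] <- cw[i, pair_of[i]]
    }
  }
  structure(list(reho = reho, dc = dc, gscorr = gscorr, vmhc = vmhc,
                 window_length = window_length, window_step = window_step,
                 subject_id = series$subject_id %||% NA_character_),
            class = "polysub_dynmaps")
}

#' @export
print.polysub_dynmaps <- function(x, ...) {
  cat("<polysub_dynmaps> ", nrow(x$reho), " parcels x ", ncol(x$reho),
      " windows (length ", x$window_length, ", step ", x$window_step, ")\n",
      sep = "")
  invisible(x)
}

#' Temporal SD of each windowed measure
#'
#' Sample SD across windows, per parcel and measure.
#'
#' @param maps a `polysub_dynmaps`.
#' @return tibble: `parcel`, `measure`, `sd`.
#' @export
temporal_sd <- function(maps) {
  if (ncol(maps$reho) < 2) abort("need >= 2 windows")
  purrr::map_dfr(c("reho", "dc", "gscorr", "vmhc"), function(m) {
    tibble::tibble(parcel = rownames(maps[[m]]) %||%
                     as.character(seq_len(nrow(maps[[m]]))),
                   measure = m,
                   sd = apply(maps[[m]], 1, sd))
  })
}

#' Volume-wise concordance of the four dynamic measures
#'
#' Per window, Kendall's W with the four measures as raters and the parcels
#' (restricted to those where all four are defined) as items; then the mean
#' and SD of the per-window series.
#'
#' @param maps a `polysub_dynmaps`.
#' @return list: `per_window` (numeric vector), `mean`, `sd`, `n_parcels`.
#' @export
volume_wise_concordance <- function(maps) {
  measures <- list(maps$reho, maps$dc, maps$gscorr, maps$vmhc)
  common <- which(Reduce(`&`, lapply(measures, function(m) {
    rowSums(is.na(m)) == 0
  })))
  if (length(common) < 2) abort("fewer than 2 parcels common to all measures")
  w <- vapply(seq_len(ncol(maps$reho)), function(wi) {
    kendalls_w(do.call(rbind, lapply(measures, function(m) m[common, wi])))
  }, numeric(1))
  list(per_window = w, mean = mean(w), sd = sd(w),
       n_parcels = length(common))
}

#' Stability of the dynamic functional architecture
#'
#' Every parcel's window-wise connectivity profile (Pearson r to each atlas
#' group's mean course) is compared across windows with Kendall's W
#' (raters = windows, items = atlas groups). Values near 1 indicate a
#' time-invariant connectivity architecture; the null level is
#' 1 / n_windows.
#'
#' @param series a `polysub_series`.
#' @param window_length,window_step window specification.
#' @param atlas_groups integer vector mapping parcels to groups, or a group
#'   count (default 8: contiguous blocks).
#' @return tibble: `parcel`, `stability`.
#' @export
functional_stability <- function(series, window_length = 30, window_step = 5,
                                 atlas_groups = 8) {
  mat <- series$mat
  p <- nrow(mat)
  if (length(atlas_groups) == 1) {
    atlas_groups <- sort(rep_len(seq_len(atlas_groups), p))
  }
  if (length(unique(atlas_groups)) < 3) abort("need >= 3 atlas groups")
  windows <- make_windows(ncol(mat), window_length, window_step)
  if (length(windows) < 2) abort("need >= 2 windows")
  groups <- sort(unique(atlas_groups))
  stab <- vapply(seq_len(p), function(i) {
    prof <- t(vapply(windows, function(idx) {
      X <- mat[, idx, drop = FALSE]
      gm <- vapply(groups, function(g) {
        colMeans(X[atlas_groups == g, , drop = FALSE])
      }, numeric(length(idx)))
      suppressWarnings(as.vector(cor(mat[i, idx], gm)))
    }, numeric(length(groups))))
    if (any(!is.finite(prof))) return(NA_real_)
    kendalls_w(prof)
  }, numeric(1))
  tibble::tibble(parcel = rownames(mat) %||% as.character(seq_len(p)),
                 stability = stab)
}

#' Per-subject dynamic summaries for a set of series
#'
#' Convenience wrapper: windowed measures, volume-wise concordance mean/SD
#' and mean temporal SD per measure for every subject.
#'
#' @param series_list list of `polysub_series`.
#' @param ... passed to [windowed_measures()].
#' @return tibble keyed by `subject_id` with `concordance_mean`,
#'   `concordance_sd`, and `tsd_<measure>` columns.
#' @export
dynamic_summaries <- function(series_list, ...) {
  purrr::map_dfr(series_list, function(s) {
    maps <- windowed_measures(s, ...)
    conc <- volume_wise_concordance(maps)
    tsd <- temporal_sd(maps)
    msd <- tapply(tsd$sd, tsd$measure, mean, na.rm = TRUE)
    tibble::tibble(subject_id = s$subject_id,
                   concordance_mean = conc$mean,
                   concordance_sd = conc$sd,
                   tsd_reho = msd[["reho"]], tsd_dc = msd[["dc"]],
                   tsd_gscorr = msd[["gscorr"]], tsd_vmhc = msd[["vmhc"]])
  })
}

#' Covariate-adjusted group comparison of dynamic summaries
#'
#' Residualizes each summary on age, site and mean framewise displacement
#' (linear model over all compared subjects), then applies two-sample
#' pooled t-tests between the two groups, with BH-FDR across the compared
#' summaries.
#'
#' @param summaries tibble from [dynamic_summaries()] joined with `subject_id`.
#' @param meta subject table carrying `subject_id`, `age`, `site`, `mean_fd`.
#' @param groups named list of two subject-id vectors to compare.
#' @param vars summary columns to test.
#' @return tibble: one row per variable with t, df, p, Cohen's d and
#'   adjusted p.
#' @export
group_compare_dynamics <- function(summaries, meta, groups,
                                   vars = c("concordance_mean",
                                            "concordance_sd", "tsd_reho",
                                            "tsd_dc", "tsd_gscorr",
                                            "tsd_vmhc")) {
  if (length(groups) != 2) abort("exactly two groups required")
  ids <- unlist(groups, use.names = FALSE)
  df <- dplyr::left_join(summaries[summaries$subject_id %in% ids, ],
                         meta[, c("subject_id", "age", "site", "mean_fd")],
                         by = "subject_id")
  if (min(lengths(groups)) < 3) abort("each group needs n >= 3")
  design_df <- data.frame(age = df$age, site = factor(df$site),
                          mean_fd = df$mean_fd)
  res <- purrr::map_dfr(vars, function(v) {
    y <- df[[v]]
    fit <- lm(y ~ age + site + mean_fd, data = design_df)
    r <- setNames(stats::residuals(fit), df$subject_id)
    a <- r[groups[[1]]]
    b <- r[groups[[2]]]
    t <- two_sample_t(a, b)
    tibble::tibble(variable = v, statistic = t$statistic, df = t$df,
                   p_value = t$p_value, cohens_d = t$effect_size)
  })
  res$p_adjusted <- bh_fdr(res$p_value)$p_adjusted
  res
}

#' Write windowed measure maps as CSV
#'
#' One `<measure>.csv` (parcels x windows) per measure.
#'
#' @param maps a `polysub_dynmaps`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dynmaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("reho", "dc", "gscorr", "vmhc")) {
    write.csv(as.data.frame(maps[[m]]), file.path(dir, paste0(m, ".csv")))
  }
  invisible(dir)
}
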