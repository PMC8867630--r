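# Subtype-level statistics. The closed forms are implemented directly so the
# test suite can verify them against independent reference implementations.

#' Two-sample t-test
#'
#' Student's pooled-variance statistic by default; Welch's unequal-variance
#' statistic with Satterthwaite degrees of freedom when
#' `equal_variance = FALSE`. Two-tailed p. Missing values are dropped.
#'
#' @param a,b numeric samples (n >= 2 each after NA removal).
#' @param equal_variance pool the variances (Student) or not (Welch).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `effect_size`
#'   (Cohen's d), `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) abort("each sample needs n >= 2")
  va <- var(a)
  vb <- var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0) {
      return(tibble::tibble(statistic = 0, df = na + nb - 2, p_value = 1,
                            effect_size = 0, n_a = na, n_b = nb))
    }
    abort("zero variance in both samples with unequal means")
  }
  if (equal_variance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- dm / se
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * pt(-abs(stat), df),
                 effect_size = cohens_d(a, b), n_a = na, n_b = nb)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param a,b numeric samples (n >= 2 each after NA removal).
#' @return `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) abort("each sample needs n >= 2")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) {
    if (mean(a) == mean(b)) return(0)
    abort("zero pooled SD with unequal means")
  }
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues raw p-values in \[0, 1\].
#' @param q significance level for the mask.
#' @return tibble with `p`, `p_adjusted` (monotone step-up values) and
#'   `significant` (`p_adjusted < q`).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
  tibble::tibble(p = pvalues, p_adjusted = adj, significant = adj < q)
}

#' Chi-square test of site composition across subtypes
#'
#' Pearson chi-square on the subtype-by-site contingency table, with
#' df = (rows - 1)(cols - 1).
#'
#' @param labels subtype labels.
#' @param sites site identifiers (same length).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_site_composition <- function(labels, sites) {
  keep <- !is.na(labels) & !is.na(sites)
  tab <- table(labels[keep], sites[keep])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has an empty row or column")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n = sum(tab))
}

#' Pearson correlation with t-transform p-value
#'
#' Pairwise-complete: rows where either variable is missing are dropped.
#'
#' @param x,y numeric vectors (n >= 3 complete pairs).
#' @return one-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(estimate = r, statistic = stat, df = df,
                 p_value = 2 * pt(-abs(stat), df), n = n)
}

#' Per-feature effect map of one group versus another
#'
#' Cohen's d, raw two-sample (pooled) t-test p, BH-FDR adjusted p and the
#' q = 0.05 significance mask, per feature.
#'
#' @param data subject table.
#' @param idx_a,idx_b row indices of the two groups.
#' @param features feature column names.
#' @param q FDR level.
#' @return tibble keyed by `feature`.
#' @export
effect_map <- function(data, idx_a, idx_b, features = NULL, q = 0.05) {
  features <- features %||% feature_names(data)
  X <- as.matrix(data[, features, drop = FALSE])
  res <- purrr::map_dfr(features, function(f) {
    t <- two_sample_t(X[idx_a, f], X[idx_b, f])
    tibble::tibble(feature = f, cohens_d = t$effect_size, p = t$p_value)
  })
  adj <- bh_fdr(res$p, q = q)
  res$p_adjusted <- adj$p_adjusted
  res$significant <- adj$significant
  res
}

# one effect map (subtype vs controls) per subtype; labels named by subject_id
effect_map_by_subtype <- function(data, labels, features = NULL, q = 0.05) {
  features <- features %||% feature_names(data)
  ctrl <- which(data$diagnosis == "control")
  ks <- sort(unique(as.integer(labels)))
  out <- lapply(ks, function(j) {
    ids <- names(labels)[labels == j]
    effect_map(data, match(ids, data$subject_id), ctrl,
               features = features, q = q)
  })
  names(out) <- paste0("subtype", ks)
  out
}

#' Subtype-level clinical and volumetric report
#'
#' For every clinical variable: pairwise two-sample t-tests
#' subtype1-vs-subtype2, controls-vs-subtype1, controls-vs-subtype2
#' (reported as columns `p_s1_s2`, `p_hc_s1`, `p_hc_s2`); a chi-square test
#' of site composition across subtypes; per-subtype TIV-score Pearson
#' correlations; and per-feature effect maps of each subtype versus
#' controls. Variables entirely missing for a group are reported as absent
#' rather than raising an error.
#'
#' @param data subject table.
#' @param labels named (by subject id) integer consensus labels for patients.
#' @param clinical_vars clinical score columns (default: the generator's).
#' @param q FDR level for the effect maps.
#' @return A `polysub_report`: tibbles `clinical`, `site_composition`,
#'   `tiv_correlations`, and the list `effect_maps`.
#' @export
subtype_report <- function(data, labels,
                           clinical_vars = c("age", "fiq", "viq", "piq",
                                             "ados_total", "ados_comm",
                                             "ados_social", "ados_rrb",
                                             "ados_severity", "adi_social",
                                             "adi_verbal", "adi_rrb",
                                             "srs_total"),
                           q = 0.05) {
  ks <- sort(unique(as.integer(labels)))
  if (length(ks) < 2) abort("need at least 2 subtypes")
  clinical_vars <- intersect(clinical_vars, names(data))
  groups <- c(list(control = which(data$diagnosis == "control")),
              lapply(setNames(ks, paste0("subtype", ks)), function(j) {
                match(names(labels)[labels == j], data$subject_id)
              }))

  cell <- function(v, idx) {
    x <- data[[v]][idx]
    x[!is.na(x)]
  }
  pair_p <- function(v, g1, g2) {
    x <- cell(v, groups[[g1]])
    y <- cell(v, groups[[g2]])
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    two_sample_t(x, y)$p_value
  }
  clinical <- purrr::map_dfr(clinical_vars, function(v) {
    ms <- vapply(names(groups), function(g) mean(cell(v, groups[[g]])),
                 numeric(1))
    sds <- vapply(names(groups), function(g) sd(cell(v, groups[[g]])),
                  numeric(1))
    ns <- vapply(names(groups), function(g) length(cell(v, groups[[g]])),
                 integer(1))
    tibble::tibble(
      variable = v,
      mean_hc = ms[["control"]], sd_hc = sds[["control"]], n_hc = ns[["control"]],
      mean_s1 = ms[["subtype1"]], sd_s1 = sds[["subtype1"]], n_s1 = ns[["subtype1"]],
      mean_s2 = ms[["subtype2"]], sd_s2 = sds[["subtype2"]], n_s2 = ns[["subtype2"]],
      p_s1_s2 = pair_p(v, "subtype1", "subtype2"),
      p_hc_s1 = pair_p(v, "control", "subtype1"),
      p_hc_s2 = pair_p(v, "control", "subtype2"),
      absent_in = paste(names(groups)[ns == 0], collapse = ",")
    )
  })

  pat_sites <- data$site[match(names(labels), data$subject_id)]
  site_comp <- chi_square_site_composition(as.integer(labels), pat_sites)

  tiv_cor <- purrr::map_dfr(setdiff(clinical_vars, "age"), function(v) {
    purrr::map_dfr(paste0("subtype", ks), function(g) {
      idx <- groups[[g]]
      ok <- !is.na(data[[v]][idx]) & !is.na(data$tiv[idx])
      if (sum(ok) < 3 || sd(data[[v]][idx][ok]) == 0) {
        return(tibble::tibble(variable = v, group = g, r = NA_real_,
                              p_value = NA_real_, n = sum(ok)))
      }
      pr <- pearson_r(data$tiv[idx], data[[v]][idx])
      tibble::tibble(variable = v, group = g, r = pr$estimate,
                     p_value = pr$p_value, n = pr$n)
    })
  })

  structure(
    list(clinical = clinical,
         site_composition = site_comp,
         tiv_correlations = tiv_cor,
         effect_maps = effect_map_by_subtype(data, labels, q = q),
         subtype_sizes = table(labels)),
    class = "polysub_report"
  )
}

#' @export
print.polysub_report <- function(x, ...) {
  cat("<polysub_report> subtype sizes:",
      paste(names(x$subtype_sizes), x$subtype_sizes, sep = "=",
            collapse = " "), "\n")
  cat("site composition: chi2 =", signif(x$site_composition$statistic, 4),
      "df =", x$site_composition$df,
      "p =", signif(x$site_composition$p_value, 3), "\n")
  print(x$clinical[, c("variable", "mean_s1", "mean_s2", "p_s1_s2",
                       "p_hc_s1", "p_hc_s2")], n = Inf)
  invisible(x)
}

#' Write a subtype report as CSV + JSON
#'
#' @param report a `polysub_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$clinical, file.path(dir, "clinical_comparison.csv"),
            row.names = FALSE)
  write.csv(report$tiv_correlations, file.path(dir, "tiv_correlations.csv"),
            row.names = FALSE)
  for (nm in names(report$effect_maps)) {
    write.csv(report$effect_maps[[nm]],
              file.path(dir, sprintf("effect_map_%s.csv", nm)),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(site_composition = report$site_composition,
         subtype_sizes = as.list(report$subtype_sizes)),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
tidy.polysub_report <- function(x, ...) {
  x$clinical
}

#' @export
glance.polysub_report <- function(x, ...) {
  tibble::tibble(n_subtypes = length(x$subtype_sizes),
                 chi2_site = x$site_composition$statistic,
                 chi2_site_p = x$site_composition$p_value,
                 n_clinical_vars = nrow(x$clinical))
}

#' Plot a per-feature effect map
#'
#' Cohen's d per feature with FDR-significant features highlighted.
#'
#' @param map tibble from [effect_map()].
#' @return a ggplot object.
#' @export
plot_effect_map <- function(map) {
  map$index <- seq_len(nrow(map))
  ggplot2::ggplot(map, ggplot2::aes(.data$index, .data$cohens_d,
                                    color = .data$significant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "feature", y = "Cohen's d",
                  color = "FDR < 0.05",
                  title = "Per-feature effect size versus controls") +
    ggplot2::theme_minimal()
}
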