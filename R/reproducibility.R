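# Split-half and leave-one-site-out validation of subtype assignments.

#' Split a cohort into two random age-matched halves
#'
#' Halves are stratified by diagnosis and site. After drawing, the age
#' distributions of the halves are compared with a two-sample t-test; the
#' draw is repeated (up to `max_attempts`) until p > `age_p_threshold`.
#'
#' @param data subject table.
#' @param seed integer seed.
#' @param max_attempts redraw budget for age matching.
#' @param age_p_threshold minimum age t-test p-value between halves.
#' @return list of two tibbles `a` and `b` partitioning `data`.
#' @export
split_half <- function(data, seed = 1L, max_attempts = 100,
                       age_p_threshold = 0.05) {
  strata <- paste(data$diagnosis, data$site)
  if (any(table(strata) < 2)) {
    abort("need >= 2 subjects per diagnosis-by-site stratum")
  }
  for (attempt in seq_len(max_attempts)) {
    half <- stratified_folds(strata, 2, child_seed(seed, "split", attempt))
    p <- two_sample_t(data$age[half == 1], data$age[half == 2])$p_value
    if (p > age_p_threshold) {
      return(list(a = data[half == 1, ], b = data[half == 2, ]))
    }
  }
  abort("could not age-match the two halves within the attempt budget")
}

#' Optimal matching of two subtype labelings
#'
#' Finds the face-label permutation that maximizes agreement. With two label
#' vectors over the same subjects, agreement is the confusion-matrix trace;
#' with two per-feature effect-size maps (features x k matrices, e.g. from
#' disjoint subject sets), agreement is the sum of matched-column Pearson
#' correlations. K is small, so the optimum is found by exhaustive search
#' over permutations.
#'
#' @param a,b either two label vectors of equal length, or two numeric
#'   matrices with one column per subtype (rows = features).
#' @return integer permutation `p` such that subtype `j` of `b` corresponds
#'   to subtype `p[j]` of `a`; attribute `score` holds the achieved
#'   agreement.
#' @export
match_subtypes <- function(a, b) {
  if (is.matrix(a) || is.data.frame(a)) {
    a <- as.matrix(a)
    b <- as.matrix(b)
    if (ncol(a) != ncol(b)) abort("unequal number of subtypes")
    score_mat <- cor(a, b)                    # k x k column correlations
  } else {
    if (length(a) != length(b)) abort("label vectors differ in length")
    k <- max(a, b, na.rm = TRUE)
    score_mat <- unclass(table(factor(a, 1:k), factor(b, 1:k)))
  }
  k <- ncol(score_mat)
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) {
    sum(score_mat[cbind(p, seq_len(k))])
  }, numeric(1))
  best <- perms[[which.max(scores)]]
  structure(best, score = max(scores))
}

#' Split-half reproducibility analysis
#'
#' Runs the full residualize + stability sweep pipeline independently on two
#' age-matched halves, matches the resulting subtypes across halves through
#' their per-feature effect maps (Cohen's d versus the half's own controls),
#' and reports the per-feature effect-direction agreement of matched
#' subtypes.
#'
#' @param data subject table (raw features; each half is residualized with
#'   its own covariate model).
#' @param k_range,folds,consensus_steps sweep parameters.
#' @param k_report subtype count at which halves are compared (default 2).
#' @param seed integer seed.
#' @param ... passed to [fit_polytope()].
#' @return list with the two `polysub_stability` profiles, the subtype
#'   matching, and `sign_agreement` (proportion of features, among those
#'   FDR-significant in either half, whose matched subtype-vs-control
#'   effects share a sign).
#' @export
split_half_analysis <- function(data, k_range = 2:8, folds = 10,
                                consensus_steps = 20, k_report = 2,
                                seed = 1L, ...) {
  halves <- split_half(data, seed = child_seed(seed, "half"))
  run <- function(half, s) {
    res <- residualize(half, fit_covariate_model(half))
    stability_sweep(res, k_range = k_range, folds = folds,
                    consensus_steps = consensus_steps,
                    seed = child_seed(seed, "sweep", s), ...)
  }
  sw_a <- run(halves$a, 1L)
  sw_b <- run(halves$b, 2L)

  dmap <- function(half, sw) {
    lab <- subtype_labels(sw, k_report)
    em <- effect_map_by_subtype(half, lab)
    list(d = sapply(seq_len(k_report), function(j) em[[j]]$cohens_d),
         sig = sapply(seq_len(k_report), function(j) em[[j]]$significant))
  }
  map_a <- dmap(halves$a, sw_a)
  map_b <- dmap(halves$b, sw_b)
  perm <- match_subtypes(map_a$d, map_b$d)
  # sign agreement over features with an FDR-significant effect in either
  # half (split-half effect maps are compared after significance masking;
  # features without any effect would contribute coin-flip signs)
  da <- map_a$d[, perm, drop = FALSE]
  sig <- map_a$sig[, perm, drop = FALSE] | map_b$sig
  if (!any(sig)) sig[] <- TRUE        # no significant features anywhere
  sign_agreement <- mean((sign(da) == sign(map_b$d))[sig])

  list(split_a = sw_a, split_b = sw_b, halves = halves,
       matching = perm, sign_agreement = sign_agreement,
       selected_k = c(a = sw_a$selected_k, b = sw_b$selected_k))
}

#' Leave-one-site-out validation of subtype labels
#'
#' For every site: a covariate model and a polytope model are fitted with
#' the site held out, the held-out patients are residualized (the unseen
#' site receives the grand-mean site offset) and assigned by the trained
#' model, and the predicted labels are compared with the full-sample
#' consensus labels after optimal label matching.
#'
#' @param data subject table (raw features).
#' @param k number of subtypes.
#' @param folds folds for the full-sample consensus run.
#' @param consensus_steps consensus partitioner repetitions.
#' @param seed integer seed.
#' @param ... passed to [fit_polytope()].
#' @return A `polysub_loso`: overall and per-site percentage overlap,
#'   predicted and consensus labels.
#' @export
leave_one_site_out <- function(data, k = 2, folds = 10, consensus_steps = 20,
                               seed = 1L, ...) {
  sites <- sort(unique(data$site))
  if (length(sites) < 2) abort("need at least 2 sites")

  # full-sample consensus labels (the reference assignment)
  full_res <- residualize(data, fit_covariate_model(data))
  runs <- cross_validated_clustering(full_res, k, folds = folds,
                                     seed = child_seed(seed, "full"), ...)
  consensus <- consensus_labels(runs, k, consensus_steps = consensus_steps,
                                seed = child_seed(seed, "cons"))

  pat_idx <- which(data$diagnosis == "patient")
  predicted <- setNames(rep(NA_integer_, length(pat_idx)),
                        data$subject_id[pat_idx])
  for (s in sites) {
    train <- data[data$site != s, ]
    heldout <- data[data$site == s, ]
    if (!any(heldout$diagnosis == "patient")) next
    cov <- fit_covariate_model(train)
    train_res <- residualize(train, cov)
    fit <- fit_polytope(train_res, k = k,
                        seed = child_seed(seed, "site", match(s, sites)), ...)
    # every site model has its own arbitrary face order; orient it on its
    # TRAINING patients against the full-sample consensus, then carry that
    # orientation to the held-out predictions (no matching on held-out data)
    train_pat <- train_res[train_res$diagnosis == "patient", ]
    perm_s <- match_subtypes(as.integer(consensus[train_pat$subject_id]),
                             predict(fit, train_pat))
    held_res <- residualize(heldout, cov, unseen_site = "zero_offset")
    held_pat <- held_res[held_res$diagnosis == "patient", ]
    predicted[held_pat$subject_id] <- perm_s[predict(fit, held_pat)]
  }

  keep <- names(consensus)[!is.na(predicted[names(consensus)])]
  matched_pred <- as.integer(predicted[keep])
  agree <- matched_pred == as.integer(consensus[keep])
  site_of <- data$site[match(keep, data$subject_id)]
  per_site <- tibble::tibble(
    site = sites,
    n_patients = as.integer(tapply(agree, factor(site_of, sites), length)),
    overlap_pct = as.numeric(tapply(agree, factor(site_of, sites), mean)) * 100
  )
  structure(
    list(overall_overlap_pct = mean(agree) * 100,
         per_site = per_site,
         predicted = setNames(matched_pred, keep),
         consensus = consensus, k = k, seed = seed),
    class = "polysub_loso"
  )
}

#' @export
print.polysub_loso <- function(x, ...) {
  cat("<polysub_loso> k = ", x$k, ", overall overlap ",
      sprintf("%.2f%%", x$overall_overlap_pct), "\n", sep = "")
  print(x$per_site, n = Inf)
  invisible(x)
}

#' @export
tidy.polysub_loso <- function(x, ...) {
  x$per_site
}

#' @export
glance.polysub_loso <- function(x, ...) {
  tibble::tibble(overall_overlap_pct = x$overall_overlap_pct,
                 n_sites = nrow(x$per_site), k = x$k)
}

#' @export
autoplot.polysub_loso <- function(object, ...) {
  ggplot2::ggplot(object$per_site,
                  ggplot2::aes(.data$site, .data$overlap_pct)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$overall_overlap_pct,
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "label overlap (%)",
                  title = "Leave-one-site-out agreement with full-sample consensus") +
    ggplot2::theme_minimal()
}
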