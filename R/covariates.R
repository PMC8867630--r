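#' Fit a linear age + site model to every feature
#'
#' Ordinary least squares of each feature on age and site indicator columns
#' (lexicographically first site as reference), fitted on either the controls
#' only (default, so that disease effects are not absorbed) or all subjects.
#'
#' @param data subject table with `age`, `site`, `diagnosis` and feature
#'   columns.
#' @param fitting_subset `"controls_only"` or `"all_subjects"`.
#' @param features feature column names (default: all `roi_` columns).
#' @return A `polysub_covmodel`: per-feature intercept, age coefficient and
#'   site offsets (reference site fixed at zero).
#' @export
fit_covariate_model <- function(data,
                                fitting_subset = c("controls_only", "all_subjects"),
                                features = NULL) {
  fitting_subset <- match.arg(fitting_subset)
  features <- features %||% feature_names(data)
  fit_rows <- if (fitting_subset == "controls_only") {
    which(data$diagnosis == "control")
  } else {
    seq_len(nrow(data))
  }
  sub <- data[fit_rows, ]
  if (length(unique(sub$age)) < 2) abort("need at least 2 distinct ages")
  site_counts <- table(sub$site)
  if (any(site_counts < 2)) {
    abort(paste0("every site needs >= 2 subjects in the fitting subset; bad: ",
                 paste(names(site_counts)[site_counts < 2], collapse = ", ")))
  }

  sites <- sort(unique(sub$site))
  design <- cbind(intercept = 1, age = sub$age,
                  site_indicators(sub$site, sites))
  if (qr(design)$rank < ncol(design)) {
    abort("rank-deficient covariate design (age/site columns collinear)")
  }
  Y <- as.matrix(sub[, features, drop = FALSE])
  beta <- qr.solve(design, Y)          # (2 + n_sites - 1) x n_features

  site_offsets <- beta[-(1:2), , drop = FALSE]
  colnames(site_offsets) <- features
  structure(
    list(features = features,
         sites = sites,
         reference_site = sites[1],
         fitting_subset = fitting_subset,
         intercept = setNames(as.numeric(beta["intercept", ]), features),
         beta_age = setNames(as.numeric(beta["age", ]), features),
         site_offsets = site_offsets),
    class = "polysub_covmodel"
  )
}

site_indicators <- function(site, sites) {
  ind <- sapply(sites[-1], function(s) as.numeric(site == s))
  if (is.null(dim(ind))) ind <- matrix(ind, ncol = length(sites) - 1)
  colnames(ind) <- sites[-1]
  ind
}

predicted_features <- function(model, data, unseen_site) {
  known <- data$site %in% model$sites
  if (!all(known) && unseen_site == "error") {
    abort(paste0("site(s) not in covariate model: ",
                 paste(unique(data$site[!known]), collapse = ", ")))
  }
  # grand-mean-center the site offsets so an unknown site receives the
  # average site effect (zero offset after centering)
  n_feat <- length(model$features)
  offsets <- rbind(0, model$site_offsets)   # reference row
  centered <- sweep(offsets, 2, colMeans(offsets))
  site_term <- matrix(0, nrow(data), n_feat)
  if (unseen_site == "zero_offset") {
    idx <- match(data$site, model$sites)
    site_term[known, ] <- centered[idx[known], , drop = FALSE]
    intercept <- model$intercept + colMeans(offsets)
  } else {
    idx <- match(data$site, model$sites)
    site_term <- offsets[idx, , drop = FALSE]
    intercept <- model$intercept
  }
  matrix(intercept, nrow(data), n_feat, byrow = TRUE) +
    outer(data$age, model$beta_age) +
    site_term
}

#' Remove fitted age and site effects from the features
#'
#' Replaces every feature column with its residual (observed minus predicted
#' under the covariate model); all metadata columns are untouched.
#'
#' @param data subject table.
#' @param model a [fit_covariate_model()] result.
#' @param unseen_site `"error"` (default) or `"zero_offset"`: how to handle a
#'   site absent from the model. With `"zero_offset"`, site offsets are
#'   grand-mean centered and the unseen site receives a zero (i.e. average)
#'   offset, as in leave-one-site-out validation.
#' @return The table with residualized features.
#' @export
residualize <- function(data, model, unseen_site = c("error", "zero_offset")) {
  unseen_site <- match.arg(unseen_site)
  stopifnot(inherits(model, "polysub_covmodel"))
  if (!all(model$features %in% names(data))) {
    abort("model features missing from table")
  }
  pred <- predicted_features(model, data, unseen_site)
  data[, model$features] <-
    as.matrix(data[, model$features, drop = FALSE]) - pred
  data
}

#' @export
print.polysub_covmodel <- function(x, ...) {
  cat("<polysub_covmodel> ", length(x$features), " features, ",
      length(x$sites), " sites (ref ", x$reference_site, "), fitted on ",
      x$fitting_subset, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a covariate model as JSON
#'
#' @param model a `polysub_covmodel`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_covariate_model()` returns the model.
#' @export
write_covariate_model <- function(model, path) {
  obj <- list(features = model$features, sites = model$sites,
              reference_site = model$reference_site,
              fitting_subset = model$fitting_subset,
              intercept = unname(model$intercept),
              beta_age = unname(model$beta_age),
              site_offsets = unname(as.matrix(model$site_offsets)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_covariate_model
#' @param path JSON file path.
#' @export
read_covariate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  so <- matrix(as.numeric(obj$site_offsets),
               nrow = length(obj$sites) - 1,
               dimnames = list(obj$sites[-1], NULL))
  structure(
    list(features = obj$features, sites = obj$sites,
         reference_site = obj$reference_site,
         fitting_subset = obj$fitting_subset,
         intercept = setNames(as.numeric(obj$intercept), obj$features),
         beta_age = setNames(as.numeric(obj$beta_age), obj$features),
         site_offsets = so),
    class = "polysub_covmodel"
  )
}
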