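#' Default clinical score specification
#'
#' One row per (score, group) giving the generating mean and SD, the target
#' Pearson correlation with total intracranial volume (TIV), and the
#' missingness rate. Defaults emulate the demographic/clinical profile of a
#' multi-site male autism case-control cohort: full-scale/verbal/performance
#' IQ for everyone, ADOS, ADI-R and SRS instruments for patients (ADOS
#' severity and ADI-R absent for controls), and a weak positive TIV
#' correlation for performance IQ in subtype 1 and for the ADOS communication
#' and social scores in subtype 2.
#'
#' @param tiv_r_piq_s1 target TIV correlation of performance IQ in subtype 1.
#' @param tiv_r_ados_s2 target TIV correlation of ADOS communication/social
#'   scores in subtype 2.
#' @return A tibble with columns `score`, `group` (`"control"`, `"subtype1"`,
#'   `"subtype2"`), `mean`, `sd`, `r_tiv`, `missing_rate`.
#' @export
default_clinical_spec <- function(tiv_r_piq_s1 = 0.24, tiv_r_ados_s2 = 0.235) {
  row <- function(score, means, sds, r = c(0, 0, 0), miss = c(0, 0, 0)) {
    tibble::tibble(
      score = score,
      group = c("control", "subtype1", "subtype2"),
      mean = means, sd = sds, r_tiv = r, missing_rate = miss
    )
  }
  dplyr::bind_rows(
    row("fiq", c(114, 111, 104), c(12.1, 15.3, 13.5)),
    row("viq", c(114, 109, 107), c(13.0, 15.7, 16.1)),
    row("piq", c(111, 112, 103), c(13.0, 14.3, 13.7),
        r = c(0, tiv_r_piq_s1, 0)),
    row("ados_total",    c(1.3, 11.8, 10.7), c(1.7, 3.6, 3.3)),
    row("ados_comm",     c(0.6, 3.7, 3.5), c(1.0, 1.6, 1.3),
        r = c(0, 0, tiv_r_ados_s2)),
    row("ados_social",   c(0.7, 8.1, 7.4), c(1.0, 2.5, 2.6),
        r = c(0, 0, tiv_r_ados_s2)),
    row("ados_rrb",      c(0.1, 2.1, 1.7), c(0.5, 1.8, 1.5)),
    row("ados_severity", c(NA, 7.7, 6.4), c(NA, 1.5, 2.4)),
    row("adi_social",    c(NA, 20.5, 19.5), c(NA, 5.0, 5.2)),
    row("adi_verbal",    c(NA, 16.3, 15.4), c(NA, 4.3, 4.6)),
    row("adi_rrb",       c(NA, 6.1, 6.4), c(NA, 2.5, 2.5)),
    row("srs_total",     c(17.7, 96.1, 90.5), c(12.9, 32.8, 32.0))
  )
}

#' Simulate a multi-site case-control cohort with planted patient subtypes
#'
#' Generates one row per subject with regional volumetric features, site and
#' age effects, planted subtype effects of opposite sign, and clinical scores
#' whose TIV correlations are induced through a shared latent factor.
#'
#' The generative model for feature `f` of subject `i` is
#' \deqn{x_{if} = \mu_f + s_{site(i)f} + \beta_{age} (age_i - \bar a) +
#'       z_i \, \delta_f \, d \, \sigma + \epsilon_{if}}
#' with baseline mean \eqn{\mu_f}, site offset drawn once per (site, feature)
#' from \eqn{N(0, site\_sd^2)}, a linear age slope, residual noise
#' \eqn{\epsilon \sim N(0, \sigma^2)}, and a planted shift of \eqn{d\sigma}
#' on the affected features (indicator \eqn{\delta_f}), positive
#' (\eqn{z = +1}) for subtype 1 and negative (\eqn{z = -1}) for subtype 2.
#' Controls have \eqn{z = 0}. Feature distributions are Gaussian (a modelling
#' assumption; see the vignette). TIV is the row sum of all features.
#'
#' Ground-truth columns (`true_subtype`, plus attributes `affected_features`
#' and `subtype_direction`) are carried for validation only and are never used
#' by analysis stages.
#'
#' @param n_hc,n_asd number of controls / patients.
#' @param n_sites number of acquisition sites.
#' @param n_features number of regional volume features.
#' @param subtype_fractions proportions of patients per subtype; must sum to 1.
#' @param effect_size_d standardized shift per affected feature (Cohen's d
#'   against the residual SD); the sign alternates by subtype.
#' @param affected_fraction proportion of features carrying the subtype shift.
#' @param age_range years; ages are uniform over this range.
#' @param beta_age volume change per year of age (same units as features).
#' @param site_sd SD of the per-site, per-feature offsets.
#' @param noise_sd residual feature SD.
#' @param baseline_mean,baseline_spread mean volume level and its
#'   between-feature spread.
#' @param clinical_spec tibble as produced by [default_clinical_spec()].
#' @param seed integer seed; regeneration with the same seed is identical.
#' @return A tibble (one row per subject): `subject_id`, `diagnosis`
#'   (`"control"`/`"patient"`), `site`, `age`, `sex`, `handedness`, clinical
#'   scores, `mean_fd`, `max_translation_mm`, `max_rotation_deg`, `tiv`,
#'   `true_subtype` (NA for controls), and feature columns `roi_001` ...
#' @export
simulate_cohort <- function(n_hc = 257, n_asd = 221, n_sites = 7,
                            n_features = 142,
                            subtype_fractions = c(0.5, 0.5),
                            effect_size_d = 0.8, affected_fraction = 0.6,
                            age_range = c(8, 45), beta_age = -5,
                            site_sd = 30, noise_sd = 100,
                            baseline_mean = 5000, baseline_spread = 800,
                            clinical_spec = default_clinical_spec(),
                            seed = 1L) {
  if (n_hc <= 0 || n_asd <= 0 || n_sites <= 0 || n_features <= 0) {
    abort("all counts must be positive")
  }
  if (abs(sum(subtype_fractions) - 1) > 1e-9) {
    abort("subtype_fractions must sum to 1")
  }
  if (any(subtype_fractions < 0)) abort("subtype_fractions must be in [0,1]")
  if (affected_fraction < 0 || affected_fraction > 1) {
    abort("affected_fraction must be in [0,1]")
  }

  n <- n_hc + n_asd
  n_subtypes <- length(subtype_fractions)
  with_seed(seed, {
    diagnosis <- c(rep("control", n_hc), rep("patient", n_asd))
    site <- sprintf("site%02d", sample(rep_len(seq_len(n_sites), n)))
    age <- runif(n, age_range[1], age_range[2])

    # deterministic subtype sizes closest to the requested fractions
    sizes <- diff(c(0, round(cumsum(subtype_fractions) * n_asd)))
    true_subtype <- c(rep(NA_integer_, n_hc),
                      sample(rep(seq_len(n_subtypes), times = sizes)))

    m_affected <- round(affected_fraction * n_features)
    affected <- sort(sample.int(n_features, m_affected))
    direction <- if (n_subtypes == 1) 1 else
      rep_len(c(1, -1), n_subtypes)        # subtype 1 up, subtype 2 down

    mu <- rnorm(n_features, baseline_mean, baseline_spread)
    site_offsets <- matrix(rnorm(n_sites * n_features, 0, site_sd),
                           n_sites, n_features,
                           dimnames = list(sprintf("site%02d", seq_len(n_sites)), NULL))

    shift <- matrix(0, n, n_features)
    z <- ifelse(is.na(true_subtype), 0, direction[true_subtype])
    shift[, affected] <- z * effect_size_d * noise_sd

    X <- matrix(mu, n, n_features, byrow = TRUE) +
      site_offsets[match(site, rownames(site_offsets)), , drop = FALSE] +
      beta_age * (age - mean(age_range)) +
      shift +
      matrix(rnorm(n * n_features, 0, noise_sd), n, n_features)
    colnames(X) <- sprintf("roi_%03d", seq_len(n_features))

    tiv <- rowSums(X)

    out <- tibble::tibble(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      diagnosis = diagnosis, site = site, age = age,
      sex = "male", handedness = "right",
      mean_fd = round(exp(rnorm(n, log(0.12), 0.5)), 4),
      max_translation_mm = round(abs(rnorm(n, 0.8, 0.7)), 3),
      max_rotation_deg = round(abs(rnorm(n, 0.8, 0.7)), 3),
      tiv = tiv, true_subtype = true_subtype
    )

    # clinical scores: shared latent factor induces the target TIV correlation
    group <- dplyr::case_when(
      diagnosis == "control" ~ "control",
      TRUE ~ paste0("subtype", pmin(true_subtype, 2))
    )
    for (sc in unique(clinical_spec$score)) {
      v <- rep(NA_real_, n)
      for (g in unique(group)) {
        spec_row <- clinical_spec[clinical_spec$score == sc &
                                    clinical_spec$group == g, ]
        if (nrow(spec_row) == 0 || is.na(spec_row$mean)) next
        idx <- which(group == g)
        z_tiv <- as.numeric(scale(tiv[idx]))
        r <- spec_row$r_tiv
        eps <- rnorm(length(idx))
        v[idx] <- spec_row$mean +
          spec_row$sd * (r * z_tiv + sqrt(1 - r^2) * eps)
        if (spec_row$missing_rate > 0) {
          drop_i <- idx[runif(length(idx)) < spec_row$missing_rate]
          v[drop_i] <- NA_real_
        }
      }
      out[[sc]] <- round(v, 1)
    }

    out <- dplyr::bind_cols(out, tibble::as_tibble(X))
    attr(out, "affected_features") <- colnames(X)[affected]
    attr(out, "subtype_direction") <- direction
    attr(out, "generator") <- list(
      effect_size_d = effect_size_d, affected_fraction = affected_fraction,
      beta_age = beta_age, site_sd = site_sd, noise_sd = noise_sd,
      baseline_mean = baseline_mean, seed = seed
    )
    out
  })
}

#' Oracle recovery of planted subtype labels
#'
#' Classifies each patient by the sign of its mean deviation (relative to the
#' control mean) over the affected features. Age and site shift every
#' feature, so when unaffected features exist their mean deviation is
#' subtracted as a per-subject reference before taking the sign. Used to
#' validate that planted structure is recoverable; never part of the
#' analysis path.
#'
#' @param data cohort from [simulate_cohort()] (two planted subtypes).
#' @return integer labels (1 = positive deviation, 2 = negative) for patients.
#' @export
oracle_subtype_labels <- function(data) {
  aff <- attr(data, "affected_features")
  if (is.null(aff)) abort("data carries no generator ground truth")
  feats <- feature_names(data)
  unaff <- setdiff(feats, aff)
  X <- as.matrix(data[, feats, drop = FALSE])
  hc_mean <- colMeans(X[data$diagnosis == "control", , drop = FALSE])
  dev <- sweep(X[data$diagnosis == "patient", , drop = FALSE], 2, hc_mean)
  score <- rowMeans(dev[, aff, drop = FALSE])
  if (length(unaff) > 0) {
    score <- score - rowMeans(dev[, unaff, drop = FALSE])
  }
  ifelse(score > 0, 1L, 2L)
}

#' Simulate parcel-level time series with subtype-dependent dynamics
#'
#' For each subject, parcel signals share a global latent course whose
#' coupling strength is modulated over time blocks; homotopic parcel pairs
#' additionally share a pair-specific latent signal. Parcel loadings on the
#' global course are heterogeneous, which makes the four windowed measures
#' (ReHo, DC, GSCorr, VMHC) rank parcels concordantly when the modulation is
#' strong. Subtype 1 receives a stronger and more stable modulation than
#' subtype 2 (higher mean, lower SD of windowed concordance); controls are
#' intermediate.
#'
#' @param subjects subject table (needs `subject_id`, `diagnosis`,
#'   `true_subtype` or consensus labels in `subtype`, `mean_fd`).
#' @param n_parcels even number of parcels; parcel p is homotopic with
#'   parcel p + n_parcels/2.
#' @param n_timepoints series length (>= block_length).
#' @param tr repetition time, seconds.
#' @param coupling homotopic-pair coupling in [0,1]: 1 duplicates the pair
#'   signal exactly, 0 leaves pairs independent.
#' @param noise_sd residual noise SD (0 gives deterministic signals).
#' @param block_length length (timepoints) of the piecewise-constant
#'   modulation blocks.
#' @param modulation named list of c(mean, sd) modulation parameters per group
#'   (`control`, `subtype1`, `subtype2`).
#' @param seed integer seed.
#' @return A named list (by subject id) of `polysub_series` objects: list with
#'   `subject_id`, `mat` (parcels x timepoints), `tr`, `homotopic_pairs`
#'   (2-column matrix), `mean_fd`.
#' @export
simulate_timeseries <- function(subjects, n_parcels = 40, n_timepoints = 120,
                                tr = 2, coupling = 0.8, noise_sd = 1,
                                block_length = 30,
                                modulation = list(control  = c(1.0, 0.25),
                                                  subtype1 = c(1.3, 0.10),
                                                  subtype2 = c(0.7, 0.45)),
                                seed = 1L) {
  if (nrow(subjects) == 0) abort("subjects must be non-empty")
  if (n_timepoints < block_length) {
    abort("n_timepoints must be at least one modulation block")
  }
  if (n_parcels %% 2 != 0) abort("n_parcels must be even")
  half <- n_parcels / 2
  pairs <- cbind(seq_len(half), seq_len(half) + half)

  group <- if ("subtype" %in% names(subjects)) {
    ifelse(subjects$diagnosis == "control", "control",
           paste0("subtype", subjects$subtype))
  } else {
    ifelse(subjects$diagnosis == "control", "control",
           paste0("subtype", pmin(subjects$true_subtype, 2)))
  }
  group[!group %in% names(modulation)] <- "control"

  with_seed(seed, {
    loadings <- runif(n_parcels, 0.2, 1.2)  # fixed across subjects
    n_blocks <- ceiling(n_timepoints / block_length)
    out <- vector("list", nrow(subjects))
    for (s in seq_len(nrow(subjects))) {
      mpar <- modulation[[group[s]]]
      g <- rnorm(n_timepoints)              # global latent course
      m_blocks <- pmax(0, rnorm(n_blocks, mpar[1], mpar[2]))
      m <- rep(m_blocks, each = block_length)[seq_len(n_timepoints)]
      pair_sig <- matrix(rnorm(half * n_timepoints), half, n_timepoints)
      mat <- matrix(0, n_parcels, n_timepoints)
      for (p in seq_len(n_parcels)) {
        ps <- pair_sig[ifelse(p > half, p - half, p), ]
        mat[p, ] <- m * loadings[p] * g +
          coupling * ps +
          noise_sd * rnorm(n_timepoints)
      }
      rownames(mat) <- sprintf("parcel_%03d", seq_len(n_parcels))
      out[[s]] <- structure(
        list(subject_id = subjects$subject_id[s], mat = mat, tr = tr,
             homotopic_pairs = pairs, mean_fd = subjects$mean_fd[s] %||% NA_real_),
        class = "polysub_series"
      )
    }
    names(out) <- subjects$subject_id
    out
  })
}

#' Write a cohort and its ground truth to disk
#'
#' The analysis table (without ground truth) goes to `cohort.csv`; the planted
#' labels go to a separate `truth.csv` that analysis stages never read.
#'
#' @param data cohort tibble.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- data[, c("subject_id", "true_subtype")]
  out <- data[, setdiff(names(data), "true_subtype")]
  write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read parcel time series with a JSON sidecar
#'
#' One `<subject_id>_timeseries.csv` (parcels x timepoints) plus
#' `<subject_id>_meta.json` (tr, homotopic pairs, mean FD) per subject.
#'
#' @param series_list list of `polysub_series`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; `read_timeseries()` returns the list.
#' @export
write_timeseries <- function(series_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in series_list) {
    base <- file.path(dir, s$subject_id)
    write.csv(as.data.frame(s$mat), paste0(base, "_timeseries.csv"))
    jsonlite::write_json(
      list(subject_id = s$subject_id, tr = s$tr,
           homotopic_pairs = unname(as.matrix(s$homotopic_pairs)),
           mean_fd = s$mean_fd),
      paste0(base, "_meta.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_timeseries
#' @param dir directory holding `*_timeseries.csv` / `*_meta.json` pairs.
#' @export
read_timeseries <- function(dir) {
  metas <- list.files(dir, pattern = "_meta\\.json$", full.names = TRUE)
  out <- lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    mat <- as.matrix(read.csv(
      sub("_meta\\.json$", "_timeseries.csv", mp), row.names = 1))
    colnames(mat) <- NULL
    pairs <- matrix(as.integer(meta$homotopic_pairs), ncol = 2)
    structure(list(subject_id = meta$subject_id, mat = mat, tr = meta$tr,
                   homotopic_pairs = pairs, mean_fd = meta$mean_fd),
              class = "polysub_series")
  })
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}
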