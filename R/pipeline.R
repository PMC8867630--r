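# Subject curation and end-to-end orchestration.

#' Curation rules for subject inclusion
#'
#' Defaults mirror a strict multi-site structural-MRI curation: males only,
#' right-handed only, full-scale IQ available and at least 80, age at most
#' 45 years, and sites with fewer than 20 patients dropped.
#'
#' @param require_male,require_right_handed flags.
#' @param min_fiq minimum full-scale IQ (missing FIQ always excludes).
#' @param max_age_years maximum age.
#' @param min_patients_per_site site-level patient-count floor.
#' @return a `polysub_rules` list.
#' @export
curation_rules <- function(require_male = TRUE, require_right_handed = TRUE,
                           min_fiq = 80, max_age_years = 45,
                           min_patients_per_site = 20) {
  if (min_fiq <= 0 || max_age_years <= 0 || min_patients_per_site <= 0) {
    abort("thresholds must be positive")
  }
  structure(list(require_male = require_male,
                 require_right_handed = require_right_handed,
                 min_fiq = min_fiq, max_age_years = max_age_years,
                 min_patients_per_site = min_patients_per_site),
            class = "polysub_rules")
}

#' Curate a subject table
#'
#' Applies the exclusion criteria in order: sex, handedness, missing or low
#' full-scale IQ, age, then sites below the patient-count floor. Counts per
#' criterion are recorded.
#'
#' @param data subject table with `sex`, `handedness`, `fiq`, `age`, `site`,
#'   `diagnosis`.
#' @param rules a [curation_rules()] object.
#' @return the retained rows; attribute `exclusion_log` tabulates exclusions
#'   per criterion in application order.
#' @export
curate <- function(data, rules = curation_rules()) {
  required <- c("sex", "handedness", "fiq", "age", "site", "diagnosis")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing metadata column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  log <- tibble::tibble(criterion = character(0), excluded = integer(0))
  note <- function(criterion, n) {
    log <<- dplyr::bind_rows(log, tibble::tibble(criterion = criterion,
                                                 excluded = as.integer(n)))
  }
  keep <- data
  if (rules$require_male) {
    drop <- is.na(keep$sex) | keep$sex != "male"
    note("not_male", sum(drop))
    keep <- keep[!drop, ]
  }
  if (rules$require_right_handed) {
    drop <- is.na(keep$handedness) | keep$handedness != "right"
    note("not_right_handed", sum(drop))
    keep <- keep[!drop, ]
  }
  drop <- is.na(keep$fiq) | keep$fiq < rules$min_fiq
  note("fiq_missing_or_low", sum(drop))
  keep <- keep[!drop, ]
  drop <- is.na(keep$age) | keep$age > rules$max_age_years
  note("age_above_max", sum(drop))
  keep <- keep[!drop, ]
  pat_per_site <- table(keep$site[keep$diagnosis == "patient"])
  small_sites <- names(pat_per_site)[pat_per_site < rules$min_patients_per_site]
  small_sites <- union(small_sites,
                       setdiff(unique(keep$site), names(pat_per_site)))
  drop <- keep$site %in% small_sites
  note("site_below_patient_floor", sum(drop))
  keep <- keep[!drop, ]
  structure(keep, exclusion_log = log)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. `stages` toggles the
#' optional downstream stages.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param cohort named list of [simulate_cohort()] arguments.
#' @param k_range,folds,consensus_steps stability-sweep parameters.
#' @param C polytope regularization.
#' @param k_report subtype count used by reporting stages.
#' @param window_length,window_step,dc_threshold,reho_k dynamics parameters.
#' @param n_repeats classification balancing repeats.
#' @param stages character subset of
#'   `c("reproducibility", "stats", "dynamics", "classification")`.
#' @param curation apply [curate()] after simulation.
#' @return a `polysub_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = list(),
                            k_range = 2:8, folds = 10, consensus_steps = 20,
                            C = 0.25, k_report = 2,
                            window_length = 30, window_step = 5,
                            dc_threshold = 0.25, reho_k = 6,
                            n_repeats = 10,
                            stages = c("reproducibility", "stats",
                                       "dynamics", "classification"),
                            curation = FALSE) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 k_range = k_range, folds = folds,
                 consensus_steps = consensus_steps, C = C,
                 k_report = k_report,
                 window_length = window_length, window_step = window_step,
                 dc_threshold = dc_threshold, reho_k = reho_k,
                 n_repeats = n_repeats, stages = stages,
                 curation = curation),
            class = "polysub_config")
}

#' Run the subtype-discovery pipeline end to end
#'
#' Simulate (or load) a cohort, optionally curate it, residualize age and
#' site effects, run the stability sweep with consensus labels, and per the
#' configured stages: reproducibility (split-half + leave-one-site-out),
#' subtype statistics, dynamic time-series measures, and subtype-aware
#' classification. Every artifact is written under `dir` together with the
#' configuration snapshot; a rerun with the same configuration is
#' identical.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created).
#' @param data optional subject table; when NULL a cohort is simulated from
#'   `config$cohort`.
#' @return invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(config, dir, data = NULL) {
  stopifnot(inherits(config, "polysub_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "log.txt")
  unlink(file.path(dir, "FAILED"))
  logline <- function(...) {
    cat(..., "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(dir, "FAILED"))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    logline(name, ": ", sprintf("%.2f s", as.numeric(Sys.time() - t0,
                                                     units = "secs")))
    res
  }
  unlink(log_path)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")

  cohort <- stage("simulate", {
    if (is.null(data)) {
      do.call(simulate_cohort,
              c(config$cohort, list(seed = child_seed(config$seed, "cohort"))))
    } else {
      data
    }
  })
  if (isTRUE(config$curation)) {
    cohort <- stage("curate", {
      cur <- curate(cohort)
      write.csv(attr(cur, "exclusion_log"),
                file.path(dir, "exclusion_log.csv"), row.names = FALSE)
      cur
    })
  }
  stage("write_cohort", write_cohort(cohort, dir))

  resid <- stage("residualize", {
    cov <- fit_covariate_model(cohort)
    write_covariate_model(cov, file.path(dir, "covariate_model.json"))
    residualize(cohort, cov)
  })

  sweep <- stage("stability_sweep", {
    sw <- stability_sweep(resid, k_range = config$k_range,
                          folds = config$folds,
                          consensus_steps = config$consensus_steps,
                          C = config$C,
                          seed = child_seed(config$seed, "sweep"))
    write_stability(sw, dir)
    sw
  })
  labels <- subtype_labels(sweep, config$k_report)

  out <- list(cohort = cohort, sweep = sweep, labels = labels)

  if ("reproducibility" %in% config$stages) {
    out$loso <- stage("leave_one_site_out", {
      r <- leave_one_site_out(cohort, k = config$k_report,
                              folds = config$folds,
                              consensus_steps = config$consensus_steps,
                              C = config$C,
                              seed = child_seed(config$seed, "loso"))
      write.csv(r$per_site, file.path(dir, "loso_per_site.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(overall_overlap_pct = r$overall_overlap_pct),
                           file.path(dir, "loso.json"), digits = NA,
                           auto_unbox = TRUE)
      r
    })
    out$split_half <- stage("split_half", {
      sh <- split_half_analysis(cohort, k_range = config$k_range,
                                folds = config$folds,
                                consensus_steps = config$consensus_steps,
                                k_report = config$k_report, C = config$C,
                                seed = child_seed(config$seed, "split"))
      jsonlite::write_json(
        list(selected_k = as.list(sh$selected_k),
             sign_agreement = sh$sign_agreement,
             profile_a = sh$split_a$profile, profile_b = sh$split_b$profile),
        file.path(dir, "split_half.json"), digits = NA, auto_unbox = TRUE)
      sh
    })
  }

  if ("stats" %in% config$stages) {
    out$report <- stage("stats", {
      rep <- subtype_report(cohort, labels)
      write_report(rep, dir)
      rep
    })
  }

  if ("dynamics" %in% config$stages) {
    out$dynamics <- stage("dynamics", {
      kept <- motion_filter(cohort)
      series <- simulate_timeseries(
        kept, seed = child_seed(config$seed, "series"))
      summ <- dynamic_summaries(series,
                                window_length = config$window_length,
                                window_step = config$window_step,
                                dc_threshold = config$dc_threshold,
                                reho_k = config$reho_k)
      write.csv(summ, file.path(dir, "dynamic_summaries.csv"),
                row.names = FALSE)
      pat_ids <- names(labels)[names(labels) %in% kept$subject_id]
      groups <- split(pat_ids, labels[pat_ids])
      cmp <- group_compare_dynamics(summ, kept,
                                    groups = groups[1:2])
      write.csv(cmp, file.path(dir, "dynamics_group_tests.csv"),
                row.names = FALSE)
      list(summaries = summ, tests = cmp)
    })
  }

  if ("classification" %in% config$stages) {
    out$classification <- stage("classification", {
      ev <- subtype_aware_evaluation(resid, labels,
                                     n_repeats = config$n_repeats,
                                     seed = child_seed(config$seed, "svm"))
      jsonlite::write_json(
        list(all_patients_pct = ev$all_patients$accuracy_pct,
             subtype1_pct = ev$subtype1$accuracy_pct,
             subtype2_pct = ev$subtype2$accuracy_pct,
             gains = as.list(ev$gains),
             weight_rank_correlation = ev$weight_rank_correlation),
        file.path(dir, "classification.json"), digits = NA,
        auto_unbox = TRUE)
      for (task in c("all_patients", "subtype1", "subtype2")) {
        write.csv(ev[[task]]$weights,
                  file.path(dir, sprintf("weights_%s.csv", task)),
                  row.names = FALSE)
      }
      ev
    })
  }

  invisible(out)
}
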