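# End-to-end pipeline: simulate (or load) -> validate -> screen -> classify
# -> analyse -> permutation test, with stage-level logging, JSON/CSV outputs
# and an md5 manifest so a rerun with the same configuration is verifiably
# identical.

#' Pipeline run configuration
#'
#' All knobs of a full run in one declarative object. When `inputs` is `NULL`
#' the cohort is simulated with the bundled generator; otherwise it must name
#' existing `dogs`, `reports` and `questionnaires` CSV paths.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory.
#' @param inputs optional named list of input CSV paths
#'   (`dogs`, `reports`, `questionnaires`).
#' @param n_dogs,n_sires,n_dams,concentration pedigree settings for the
#'   simulated cohort.
#' @param cohort,risk,reports,questionnaires generator configurations
#'   ([cohort_config()], [risk_params()], [report_config()],
#'   [questionnaire_config()]).
#' @param keyword_set screening keywords.
#' @param overrides optional manual-review override data frame
#'   (`dog_id`, `decision`).
#' @param demote_excluded classification flag, see [classify_dog()].
#' @param level confidence level used throughout.
#' @param n_perm permutation samples; `0` skips the permutation stage.
#' @param weighting contribution-statistic weighting.
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("limbertail_run_"),
                            inputs = NULL,
                            n_dogs = 1500, n_sires = 300, n_dams = 400,
                            concentration = 1,
                            cohort = cohort_config(), risk = risk_params(),
                            reports = report_config(),
                            questionnaires = questionnaire_config(),
                            keyword_set = default_keywords(),
                            overrides = NULL, demote_excluded = FALSE,
                            level = 0.95, n_perm = 10000,
                            weighting = c("offspring_weighted", "plain_mean")) {
  if (missing(seed)) abort_arg("a seed is mandatory")
  weighting <- match.arg(weighting)
  if (!is.null(inputs)) {
    need <- c("dogs", "reports", "questionnaires")
    if (!all(need %in% names(inputs))) {
      abort_arg("inputs must name paths: %s", paste(need, collapse = ", "))
    }
    for (p in unlist(inputs[need])) {
      if (!file.exists(p)) abort_arg("input file not found: %s", p)
    }
  }
  if (!is_count(n_perm)) abort_arg("n_perm must be a non-negative integer")
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar keys mirror the arguments of [pipeline_config()]; nested generator
#' settings may be given under `cohort`, `risk`, `reports` and
#' `questionnaires` and are spliced into the corresponding configuration
#' constructors.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file is read (e.g. from CLI flags).
#' @return A [pipeline_config()] object.
#' @export
load_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  dots <- list(...)
  raw[names(dots)] <- dots
  for (nm in c("cohort", "risk", "reports", "questionnaires")) {
    if (!is.null(raw[[nm]]) && !inherits(raw[[nm]], c("cohort_config", "risk_params",
                                                      "report_config", "questionnaire_config"))) {
      ctor <- switch(nm, cohort = cohort_config, risk = risk_params,
                     reports = report_config, questionnaires = questionnaire_config)
      raw[[nm]] <- do.call(ctor, raw[[nm]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Case-control analysis of a classified cohort
#'
#' Computes the study estimates from the dog table, questionnaire table and
#' final case/control status: cumulative incidence among provisional controls
#' (promoted controls over provisional controls, with a Clopper-Pearson
#' interval), exact conditional odds ratios with Fisher tests for swimming
#' and working-dog status, single-predictor logistic fits of case status on
#' latitude and on longitude (plus a joint fit), and descriptive summaries of
#' first-incident duration, pain and quality-of-life scores with their
#' Pearson correlation.
#'
#' @param dogs dog table ([read_dogs()] layout).
#' @param questionnaires questionnaire table.
#' @param status final-status data frame from [reclassify_cohort()].
#' @param level confidence level.
#' @return Named list of estimates.
#' @export
analyse_cohort <- function(dogs, questionnaires, status, level = 0.95) {
  q <- merge(questionnaires, status, by = "dog_id")
  q <- merge(q, dogs[c("dog_id", "purpose", "latitude", "longitude")], by = "dog_id")
  is_case <- q$final == "case"
  is_ctrl <- q$final == "control"
  out <- list(n_cases = sum(is_case), n_controls = sum(is_ctrl))

  n_prov_controls <- sum(q$provisional == "control")
  n_promoted <- sum(q$provisional == "control" & is_case)
  out$incidence <- if (n_prov_controls > 0) {
    cumulative_incidence(n_promoted, n_prov_controls, level)
  }

  tab_from <- function(exposed) {
    table2x2(sum(is_case & exposed), sum(is_case & !exposed),
             sum(is_ctrl & exposed), sum(is_ctrl & !exposed))
  }
  swim <- q$swims_ever %in% TRUE
  work <- q$purpose %in% c("working", "gundog_and_pet")
  out$swimming_or <- tryCatch(exact_or(tab_from(swim), level), error = function(e) NULL)
  out$working_or <- tryCatch(exact_or(tab_from(work), level), error = function(e) NULL)

  arm <- is_case | is_ctrl
  y <- as.integer(is_case[arm])
  fit_or_null <- function(pred) {
    tryCatch(fit_logistic(y, pred, level), error = function(e) NULL)
  }
  out$latitude_fit <- fit_or_null(data.frame(latitude = q$latitude[arm]))
  out$longitude_fit <- fit_or_null(data.frame(longitude = q$longitude[arm]))
  out$joint_fit <- fit_or_null(data.frame(latitude = q$latitude[arm],
                                          longitude = q$longitude[arm]))

  dur <- suppressWarnings(recode_duration(q$duration_category[is_case]))
  dur <- dur[!is.na(dur)]
  out$duration <- if (length(dur) >= 2) summarise_numeric(dur, level)
  pain <- q$pain_score[is_case]; qol <- q$qol_score[is_case]
  keep <- !is.na(pain)
  out$pain <- if (sum(keep) >= 2) summarise_numeric(pain[keep], level)
  keep2 <- !is.na(qol)
  out$qol <- if (sum(keep2) >= 2) summarise_numeric(qol[keep2], level)
  both <- !is.na(pain) & !is.na(qol)
  out$pain_qol_correlation <- if (sum(both) >= 3 &&
                                  stats::sd(pain[both]) > 0 && stats::sd(qol[both]) > 0) {
    pearson_correlation(pain[both], qol[both])
  }
  # answered-no-but-scored-pain inconsistencies are reported, never corrected
  out$pain_inconsistencies <- sum(q$pain_reported %in% c("no", "unsure") &
                                    !is.na(q$pain_score) & q$pain_score > 0)
  out
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Run the full pipeline
#'
#' Executes simulate/load -> validate -> screen -> classify -> analyse ->
#' permutation test, writing every stage output under `config$out_dir` and an
#' md5 manifest of all files. A failing stage aborts with the stage named,
#' after moving partial outputs under a `failed/` prefix. Reruns with the
#' same configuration reproduce an identical manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return List of class `"run_report"`: the stage results plus `paths` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort_arg("config must be a pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[limbertail] ", sprintf(...))
  stage <- "setup"
  result <- tryCatch({
    statuses <- NULL
    if (is.null(config$inputs)) {
      stage <- "simulate"
      ped <- generate_pedigree(config$n_dogs, config$n_sires, config$n_dams,
                               config$concentration, seed = config$seed)
      dogs <- generate_cohort(ped, config$cohort, seed = config$seed + 1L)
      statuses <- simulate_case_status(dogs, config$risk, seed = config$seed + 2L)
      reports <- render_free_text_reports(dogs, statuses, config$reports,
                                          seed = config$seed + 3L)
      quest <- generate_questionnaires(dogs, statuses, config$questionnaires,
                                       seed = config$seed + 4L)
      write_cohort_tables(config$out_dir, dogs, reports, quest, statuses)
      log_stage("simulated %d dogs, %d reports (%d truly affected)",
                nrow(dogs), nrow(reports), sum(statuses$status$affected))
    } else {
      stage <- "load"
      dogs <- read_dogs(config$inputs$dogs)
      reports <- read_reports(config$inputs$reports)
      quest <- read_questionnaires(config$inputs$questionnaires)
      log_stage("loaded %d dogs, %d reports, %d questionnaires",
                nrow(dogs), nrow(reports), nrow(quest))
    }

    stage <- "validate"
    if (is.null(config$inputs)) {
      violations <- validate_inputs(file.path(config$out_dir, "dogs.csv"),
                                    file.path(config$out_dir, "reports.csv"),
                                    file.path(config$out_dir, "questionnaires.csv"))
    } else {
      violations <- validate_inputs(config$inputs$dogs, config$inputs$reports,
                                    config$inputs$questionnaires)
    }
    if (length(violations)) {
      abort_arg("input validation failed:\n%s", paste("-", violations, collapse = "\n"))
    }
    log_stage("inputs valid")

    stage <- "screen"
    screen <- screen_cohort(reports, config$keyword_set, config$overrides, config$level)
    write_csv_utf8(screen$results, file.path(config$out_dir, "screen_results.csv"))
    write_csv_utf8(screen$needs_review, file.path(config$out_dir, "needs_review.csv"))
    log_stage("screened %d reports: %d candidate dogs, %d incidents, %d for review",
              nrow(reports), screen$n_dogs, screen$n_incidents, nrow(screen$needs_review))

    stage <- "classify"
    provisional <- data.frame(
      dog_id = quest$dog_id,
      provisional = ifelse(quest$dog_id %in% screen$dogs$dog_id, "case", "control"),
      stringsAsFactors = FALSE
    )
    recl <- reclassify_cohort(quest, provisional, config$demote_excluded)
    write_csv_utf8(recl$status, file.path(config$out_dir, "final_status.csv"))
    jsonlite::write_json(recl$transitions, file.path(config$out_dir, "transitions.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("classified: %d cases, %d controls, %d excluded",
              recl$transitions$n_cases, recl$transitions$n_controls,
              recl$transitions$n_excluded)

    stage <- "analyse"
    analysis <- analyse_cohort(dogs, quest, recl$status, config$level)
    analysis$screening <- list(
      n_incidents = screen$n_incidents, n_dogs = screen$n_dogs,
      vet_missed = screen$vet_missed,
      incident_multiplicity = as.list(screen$incident_multiplicity)
    )
    # reference substage: the published worked-example tables, independent of
    # the simulated cohort
    ref <- limber_example_tables()
    analysis$reference <- list(
      swimming = exact_or(ref$swimming, config$level),
      working = exact_or(ref$working, config$level),
      binomial = lapply(ref$binomial, function(kn) {
        clopper_pearson_ci(kn[["k"]], kn[["n"]], config$level)
      })
    )
    jsonlite::write_json(strip_classes(analysis), file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    log_stage("analysis written")

    stage <- "permtest"
    perm <- NULL
    if (config$n_perm > 0) {
      case_ids <- recl$status$dog_id[recl$status$final == "case"]
      if (length(case_ids) >= 2 && length(case_ids) < nrow(dogs)) {
        perm <- lapply(c(sire = "sire", dam = "dam"), function(axis) {
          permutation_test(case_ids, dogs$dog_id, dogs, axis,
                           n_perm = config$n_perm, seed = config$seed + 5L,
                           weighting = config$weighting)
        })
        jsonlite::write_json(
          lapply(perm, function(p) strip_classes(p[setdiff(names(p), "null_values")])),
          file.path(config$out_dir, "permutation.json"),
          auto_unbox = TRUE, digits = NA, force = TRUE)
        write_csv_utf8(data.frame(sire = perm$sire$null_values,
                                  dam = perm$dam$null_values),
                       file.path(config$out_dir, "null_distribution.csv"))
        log_stage("permutation test: sire p = %.4g, dam p = %.4g",
                  perm$sire$p_value, perm$dam$p_value)
      } else {
        log_stage("permutation stage skipped: degenerate case set")
      }
    } else {
      log_stage("permutation stage skipped (n_perm = 0)")
    }

    stage <- "report"
    report_path <- file.path(config$out_dir, "report.md")
    writeLines(render_report(analysis, recl$transitions, perm, config), report_path)

    files <- sort(list.files(config$out_dir, full.names = TRUE, recursive = TRUE))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(list(screen = screen, classification = recl, analysis = analysis,
                   permutation = perm, manifest = manifest,
                   out_dir = config$out_dir, config = config),
              class = "run_report")
  }, error = function(e) {
    failed <- file.path(config$out_dir, "failed")
    dir.create(failed, showWarnings = FALSE)
    for (f in list.files(config$out_dir, full.names = TRUE)) {
      if (!dir.exists(f)) file.rename(f, file.path(failed, basename(f)))
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

fmt_or <- function(x, digits = 1) {
  if (is.null(x)) return("not estimable")
  sprintf("%.*f (%g%% CI %.*f to %.*f), p = %.2f", digits, x$or_point,
          100 * x$level, digits, x$ci_low, digits, x$ci_high, x$p_value)
}

fmt_binom <- function(x, digits = 1) {
  if (is.null(x)) return("not estimable")
  sprintf("%.*f%% (%g%% CI %.*f to %.*f%%)", digits, 100 * x$point,
          100 * x$level, digits, 100 * x$ci_low, digits, 100 * x$ci_high)
}

render_report <- function(analysis, transitions, perm, config) {
  lines <- c(
    "# Limber tail cohort analysis",
    "",
    sprintf("Seed %d; confidence level %g%%.", config$seed, 100 * config$level),
    "",
    "## Classification",
    sprintf("- %d questionnaires: %d cases, %d controls, %d excluded (%d provisional cases confirmed, %d excluded from the case arm; %d controls promoted).",
            transitions$n_responses, transitions$n_cases, transitions$n_controls,
            transitions$n_excluded, transitions$cases_confirmed,
            transitions$cases_excluded, transitions$controls_promoted),
    "",
    "## Estimates",
    sprintf("- Cumulative incidence among provisional controls: %s",
            if (is.null(analysis$incidence)) "not estimable" else fmt_binom(analysis$incidence$estimate)),
    sprintf("- Swimming odds ratio (exact conditional): %s", fmt_or(analysis$swimming_or)),
    sprintf("- Working-dog odds ratio (exact conditional): %s", fmt_or(analysis$working_or)),
    if (!is.null(analysis$latitude_fit)) {
      sprintf("- Latitude: OR %.2f per degree (%g%% CI %.2f to %.2f)%s",
              analysis$latitude_fit$or[["latitude"]], 100 * config$level,
              analysis$latitude_fit$or_ci_low[["latitude"]],
              analysis$latitude_fit$or_ci_high[["latitude"]],
              if (analysis$latitude_fit$separation) " [separation flagged]" else "")
    } else "- Latitude: not estimable",
    if (!is.null(analysis$duration)) {
      sprintf("- Mean first-incident duration: %.1f days (%g%% CI %.1f to %.1f)",
              analysis$duration$mean, 100 * config$level,
              analysis$duration$ci_low, analysis$duration$ci_high)
    },
    if (!is.null(analysis$pain)) {
      sprintf("- Mean pain score %.1f/10; mean quality-of-life impact %.1f/10; Pearson correlation %s.",
              analysis$pain$mean,
              if (is.null(analysis$qol)) NA_real_ else analysis$qol$mean,
              if (is.null(analysis$pain_qol_correlation)) "not estimable"
              else sprintf("%.2f", analysis$pain_qol_correlation))
    },
    sprintf("- Pain answers of no/unsure with a non-zero pain score (reported as-is): %d.",
            analysis$pain_inconsistencies),
    "- Mixed-effects comparisons of height/weight/exercise: not implemented.",
    "",
    "## Familial clustering",
    if (is.null(perm)) {
      "- Permutation stage skipped."
    } else {
      vapply(names(perm), function(axis) {
        p <- perm[[axis]]
        sprintf("- %s axis: observed %.3f vs null band [%.3f, %.3f], p = %.4g%s",
                axis, p$observed$statistic, p$pct_2_5, p$pct_97_5, p$p_value,
                if (p$significant) " - significant familial clustering" else "")
      }, "")
    },
    "",
    "## Reference worked example",
    sprintf("- Swimming table: OR %s", fmt_or(analysis$reference$swimming)),
    sprintf("- Working table: OR %s", fmt_or(analysis$reference$working)),
    sprintf("- Questionnaire incidence 9/93: %s",
            fmt_binom(analysis$reference$binomial$questionnaire_incidence)),
    sprintf("- Non-response sensitivity 9/127: %s",
            fmt_binom(analysis$reference$binomial$nonresponse_sensitivity)),
    sprintf("- Whole-cohort incidence 43/6000: %s",
            fmt_binom(analysis$reference$binomial$cohort_incidence)),
    sprintf("- Missed by practice records 32/43: %s",
            fmt_binom(analysis$reference$binomial$vet_missed))
  )
  unlist(lines)
}

#' @export
print.run_report <- function(x, ...) {
  cat("limbertail pipeline run in", x$out_dir, "\n")
  tr <- x$classification$transitions
  cat(sprintf("%d cases / %d controls; swimming OR %s\n", tr$n_cases, tr$n_controls,
              fmt_or(x$analysis$swimming_or)))
  if (!is.null(x$permutation)) {
    cat(sprintf("sire clustering p = %.4g\n", x$permutation$sire$p_value))
  }
  invisible(x)
}
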