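# Stage-2 case/control classification from questionnaire sign profiles.
#
# Case definition: some degree of tail limpness (limp at the end or along the
# whole length) with no alternative cause reported. "Unsure" answers on the
# limpness signs count as "no" - case status requires positively reported
# flaccidity. An attribution to any concrete alternative cause (injury, anal
# glands, other) vetoes case status even when limpness is reported.
#
# Provisional cases whose questionnaire shows no limpness are excluded from
# the case arm. By default they are retained in the control arm (the
# accounting under which 31 provisional cases and 93 provisional controls
# yield 38 cases and 86 controls); `demote_excluded = TRUE` instead assigns
# them a three-way "excluded" status that appears in neither arm.

sign_cols <- c("sign_limp_end", "sign_limp_length", "sign_stiff_base",
               "sign_hair_on_end", "sign_painful")

check_response <- function(response) {
  missing_cols <- setdiff(c(sign_cols, "attribution"), names(response))
  if (length(missing_cols)) {
    abort_arg("questionnaire response lacks field(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (col in sign_cols) {
    bad <- !(response[[col]] %in% c("yes", "no", "unsure"))
    if (any(bad)) abort_arg("%s must be yes/no/unsure", col)
  }
  invisible(response)
}

#' Classify one dog from its questionnaire response
#'
#' @param response list or one-row data frame with the five `sign_*` fields
#'   (`yes`/`no`/`unsure`) and `attribution`
#'   (`none`/`injury`/`anal_glands`/`other_cause`).
#' @param provisional `"case"` or `"control"`: the status assigned by
#'   routine-report screening before the questionnaire.
#' @param demote_excluded if `TRUE`, a provisional case without limpness gets
#'   `final = "excluded"` rather than joining the control arm.
#' @return List of class `"final_status"` with `dog_id`, `provisional`,
#'   `final` (`case`/`control`/`excluded`) and `reason`, one of
#'   `limpness_confirmed`, `no_limpness`, `attributed_other_cause`,
#'   `signs_without_limpness`, `no_signs`.
#' @examples
#' classify_dog(list(sign_limp_end = "no", sign_limp_length = "yes",
#'                   sign_stiff_base = "no", sign_hair_on_end = "no",
#'                   sign_painful = "yes", attribution = "none"),
#'              provisional = "control")
#' @export
classify_dog <- function(response, provisional, demote_excluded = FALSE) {
  if (is.data.frame(response)) response <- as.list(response[1, , drop = FALSE])
  check_response(response)
  if (!provisional %in% c("case", "control")) abort_arg("provisional must be case or control")
  limp <- response$sign_limp_end == "yes" || response$sign_limp_length == "yes"
  any_sign <- any(vapply(sign_cols, function(cl) response[[cl]] == "yes", logical(1)))
  attributed <- !response$attribution %in% "none"
  if (limp && !attributed) {
    final <- "case"; reason <- "limpness_confirmed"
  } else if (attributed && any_sign) {
    final <- "control"; reason <- "attributed_other_cause"
  } else if (!limp && provisional == "case") {
    final <- if (demote_excluded) "excluded" else "control"
    reason <- "no_limpness"
  } else if (any_sign) {
    final <- "control"; reason <- "signs_without_limpness"
  } else {
    final <- "control"; reason <- "no_signs"
  }
  structure(list(dog_id = response$dog_id %||% NA_character_,
                 provisional = provisional, final = final, reason = reason),
            class = "final_status")
}

#' @export
print.final_status <- function(x, ...) {
  cat(sprintf("%s: provisional %s -> final %s (%s)\n",
              if (is.na(x$dog_id)) "dog" else x$dog_id,
              x$provisional, x$final, x$reason))
  invisible(x)
}

#' Reclassify a questionnaire cohort and tally the status transitions
#'
#' Applies [classify_dog()] to every response and summarises the movement
#' between provisional and final status: provisional cases confirmed or
#' excluded, provisional controls retained or promoted.
#'
#' @param responses data frame of questionnaire responses (must carry
#'   `dog_id`).
#' @param provisional_map named character vector or data frame
#'   (`dog_id`, `provisional`) giving each dog's provisional status.
#' @param demote_excluded passed to [classify_dog()].
#' @return List of class `"reclassification"`: `status`, a data frame with
#'   `dog_id`, `provisional`, `final`, `reason`; and `transitions`, a list of
#'   counts (`n_responses`, `provisional_cases`, `provisional_controls`,
#'   `cases_confirmed`, `cases_excluded`, `controls_promoted`,
#'   `controls_retained`, `n_cases`, `n_controls`, `n_excluded`).
#' @export
reclassify_cohort <- function(responses, provisional_map, demote_excluded = FALSE) {
  if (!"dog_id" %in% names(responses)) abort_arg("responses must carry dog_id")
  if (is.data.frame(provisional_map)) {
    pm <- stats::setNames(provisional_map$provisional, provisional_map$dog_id)
  } else {
    pm <- provisional_map
  }
  if (nrow(responses) == 0L) {
    status <- data.frame(dog_id = character(0), provisional = character(0),
                         final = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  } else {
    prov <- pm[responses$dog_id]
    if (anyNA(prov)) {
      abort_arg("no provisional status for dog(s): %s",
                paste(responses$dog_id[is.na(prov)], collapse = ", "))
    }
    rows <- lapply(seq_len(nrow(responses)), function(i) {
      fs <- classify_dog(responses[i, , drop = FALSE], prov[[i]], demote_excluded)
      data.frame(dog_id = fs$dog_id, provisional = fs$provisional,
                 final = fs$final, reason = fs$reason, stringsAsFactors = FALSE)
    })
    status <- do.call(rbind, rows)
  }
  tr <- list(
    n_responses = nrow(status),
    provisional_cases = sum(status$provisional == "case"),
    provisional_controls = sum(status$provisional == "control"),
    cases_confirmed = sum(status$provisional == "case" & status$final == "case"),
    cases_excluded = sum(status$provisional == "case" & status$final != "case"),
    controls_promoted = sum(status$provisional == "control" & status$final == "case"),
    controls_retained = sum(status$provisional == "control" & status$final == "control"),
    n_cases = sum(status$final == "case"),
    n_controls = sum(status$final == "control"),
    n_excluded = sum(status$final == "excluded")
  )
  structure(list(status = status, transitions = tr), class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  tr <- x$transitions
  cat(sprintf(
    "%d responses: %d provisional cases (%d confirmed, %d excluded from case arm), %d provisional controls (%d promoted)\n",
    tr$n_responses, tr$provisional_cases, tr$cases_confirmed, tr$cases_excluded,
    tr$provisional_controls, tr$controls_promoted))
  cat(sprintf("final: %d cases, %d controls, %d excluded\n",
              tr$n_cases, tr$n_controls, tr$n_excluded))
  invisible(x)
}

#' Recode an owner-reported duration category to days
#'
#' Vague categories map to fixed values: `"a few hours"` to 0.125 days
#' (three hours), `"a few days"` to 3 days, `"a week or more"` to 8 days.
#' Explicit day counts (e.g. `"2 days"`, `"about 10 days"`, or bare numbers)
#' pass through as the stated number. Unrecognised categories become `NA`
#' with a warning so they are excluded from summaries rather than silently
#' miscoded.
#'
#' @param duration_category character (or numeric) vector.
#' @return Numeric vector of durations in days.
#' @examples
#' recode_duration(c("a few hours", "a few days", "a week or more", "2 days"))
#' @export
recode_duration <- function(duration_category) {
  if (is.numeric(duration_category)) return(as.numeric(duration_category))
  x <- tolower(trimws(as.character(duration_category)))
  out <- rep(NA_real_, length(x))
  out[grepl("few hours|couple of hours", x)] <- 3 / 24
  out[grepl("few days|couple of days", x)] <- 3
  out[grepl("week or more|a week|over a week", x)] <- 8
  num <- is.na(out) & grepl("^(about |around |approx\\.? )?[0-9]+(\\.[0-9]+)?( days?)?$", x)
  out[num] <- as.numeric(sub("^\\D*([0-9]+(\\.[0-9]+)?).*$", "\\1", x[num]))
  bad <- is.na(out) & !is.na(x) & x != ""
  if (any(bad)) {
    warning("unrecognised duration categor", if (sum(bad) > 1) "ies: " else "y: ",
            paste(unique(x[bad]), collapse = ", "), " (excluded from summaries)",
            call. = FALSE)
  }
  out
}
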