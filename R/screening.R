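# Stage-1 keyword screening of free-text illness reports.
#
# A report is a candidate limber-tail incident when its text contains "tail"
# together with at least one keyword from a fixed stem list; "tail" without
# any keyword routes the report to a manual-review queue. Matching is
# case-insensitive plain substring matching: the stems only make sense as
# substrings ('limb' is meant to catch "limber", 'swim' catches "swimming"),
# and the review queue plus an override file covers the occasional false
# positive such as "climbing".

#' Default screening keyword stems
#'
#' The thirteen stems used alongside "tail" to flag candidate incidents.
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  c("cold", "dead", "droopy", "drop", "limb", "limber", "limp",
    "rudder", "staved", "stiff", "stride", "swim", "swimmers")
}

screen_text <- function(text, keyword_set) {
  text_l <- tolower(text %||% "")
  has_tail <- grepl("tail", text_l, fixed = TRUE)
  hits <- keyword_set[vapply(tolower(keyword_set),
                             function(k) grepl(k, text_l, fixed = TRUE),
                             logical(1))]
  matched <- has_tail && length(hits) > 0L
  list(matched = matched,
       matched_keywords = if (matched) hits else character(0),
       needs_review = has_tail && !matched)
}

#' Screen one illness report for candidate limber-tail wording
#'
#' @param report a list or one-row data frame with at least `text` (and
#'   usually `dog_id`, `report_date`, `vet_visit`), or a single character
#'   string.
#' @param keyword_set non-empty character vector of keyword stems; defaults
#'   to [default_keywords()].
#' @return List of class `"screen_result"`: `dog_id` (if supplied),
#'   `matched`, `matched_keywords`, `needs_review`. Empty text is neither
#'   matched nor queued for review.
#' @examples
#' screen_report("Limber tail after a cold swim")
#' screen_report("She had a problem with her tail, she couldn't wag it")
#' @export
screen_report <- function(report, keyword_set = default_keywords()) {
  if (!is.character(keyword_set) || length(keyword_set) == 0L) {
    abort_arg("keyword_set must be a non-empty character vector")
  }
  if (is.character(report)) report <- list(text = report)
  if (is.data.frame(report)) report <- as.list(report[1, , drop = FALSE])
  if (is.null(report$text)) abort_arg("report must carry a text field")
  res <- screen_text(report$text, keyword_set)
  structure(c(list(dog_id = report$dog_id %||% NA_character_), res),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("%s: %s%s\n",
              if (is.na(x$dog_id)) "report" else x$dog_id,
              if (x$matched) paste("matched on", paste(x$matched_keywords, collapse = ", "))
              else "not matched",
              if (x$needs_review) " (tail mentioned - manual review)" else ""))
  invisible(x)
}

#' Screen a whole report table and summarise candidate dogs
#'
#' Applies the keyword rule to every report, groups matched reports into
#' incidents per dog (reports by one dog on the same date are one incident),
#' and summarises veterinary presentation: the number of candidate dogs
#' whose incidents never involved a veterinary visit, with a Clopper-Pearson
#' interval - the fraction a practice-records study would miss.
#'
#' Manual review outcomes can be injected through `overrides`, a data frame
#' with columns `dog_id` and `decision` (`"include"`/`"exclude"`): included
#' dogs join the candidate list even without a keyword match (their
#' tail-only reports count as incidents), excluded dogs are dropped.
#'
#' @param reports data frame with columns `dog_id`, `report_date`, `text`,
#'   `vet_visit`.
#' @param keyword_set keyword stems, default [default_keywords()].
#' @param overrides optional review-decision data frame (see above).
#' @param level confidence level for the missed-fraction interval.
#' @return List of class `"screen_summary"`:
#'   `results` (per-report data frame with `matched`, `matched_keywords`,
#'   `needs_review`, `included`), `dogs` (per-candidate-dog data frame with
#'   `n_incidents`, `any_vet_visit`), `n_incidents`, `n_dogs`,
#'   `incident_multiplicity` (table of dogs by incident count),
#'   `needs_review` (the unmatched "tail" reports), and `vet_missed`
#'   (a [clopper_pearson_ci()] of the fraction of candidate dogs with no
#'   veterinary visit).
#' @export
screen_cohort <- function(reports, keyword_set = default_keywords(),
                          overrides = NULL, level = 0.95) {
  req <- c("dog_id", "report_date", "text", "vet_visit")
  missing_cols <- setdiff(req, names(reports))
  if (length(missing_cols)) abort_arg("reports lack column(s): %s", paste(missing_cols, collapse = ", "))
  n <- nrow(reports)
  scr <- lapply(seq_len(n), function(i) screen_text(reports$text[i], keyword_set))
  results <- data.frame(
    dog_id = reports$dog_id,
    report_date = reports$report_date,
    vet_visit = reports$vet_visit,
    matched = vapply(scr, `[[`, logical(1), "matched"),
    matched_keywords = vapply(scr, function(s) paste(s$matched_keywords, collapse = ";"), ""),
    needs_review = vapply(scr, `[[`, logical(1), "needs_review"),
    stringsAsFactors = FALSE
  )
  results$included <- results$matched
  if (!is.null(overrides)) {
    if (!all(c("dog_id", "decision") %in% names(overrides))) {
      abort_arg("overrides need columns dog_id and decision")
    }
    bad <- setdiff(overrides$decision, c("include", "exclude"))
    if (length(bad)) abort_arg("unknown override decision(s): %s", paste(bad, collapse = ", "))
    inc <- overrides$dog_id[overrides$decision == "include"]
    exc <- overrides$dog_id[overrides$decision == "exclude"]
    # included dogs contribute their tail-bearing reports as incidents
    results$included <- (results$included |
                           (results$dog_id %in% inc &
                              (results$matched | results$needs_review))) &
      !(results$dog_id %in% exc)
  }
  cand <- results[results$included, , drop = FALSE]
  if (nrow(cand)) {
    key <- paste(cand$dog_id, cand$report_date) # same dog + date = one incident
    cand <- cand[!duplicated(key), , drop = FALSE]
    inc_per_dog <- tapply(rep(1L, nrow(cand)), cand$dog_id, sum)
    vet_per_dog <- tapply(cand$vet_visit, cand$dog_id, any)
    dogs <- data.frame(dog_id = names(inc_per_dog),
                       n_incidents = as.integer(inc_per_dog),
                       any_vet_visit = as.logical(vet_per_dog[names(inc_per_dog)]),
                       stringsAsFactors = FALSE, row.names = NULL)
    dogs <- dogs[order(dogs$dog_id), , drop = FALSE]
    rownames(dogs) <- NULL
  } else {
    dogs <- data.frame(dog_id = character(0), n_incidents = integer(0),
                       any_vet_visit = logical(0), stringsAsFactors = FALSE)
  }
  n_dogs <- nrow(dogs)
  vet_missed <- if (n_dogs > 0) {
    clopper_pearson_ci(sum(!dogs$any_vet_visit), n_dogs, level)
  } else NULL
  structure(
    list(results = results,
         dogs = dogs,
         n_incidents = sum(dogs$n_incidents),
         n_dogs = n_dogs,
         incident_multiplicity = if (n_dogs) table(dogs$n_incidents) else table(integer(0)),
         needs_review = results[results$needs_review, , drop = FALSE],
         vet_missed = vet_missed),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("%d candidate incidents across %d dogs; %d report(s) queued for manual review\n",
              x$n_incidents, x$n_dogs, nrow(x$needs_review)))
  if (!is.null(x$vet_missed)) {
    cat("fraction of candidate dogs never presented to a veterinarian: ")
    print(x$vet_missed)
  }
  invisible(x)
}
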