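# Templated owner free-text illness reports.
#
# Three template classes drive the screening-stage evaluation:
#  * "keyword"      - tail phrases carrying at least one screening keyword,
#                     phrased like the owner descriptions the cohort received
#                     (limp/limber tail, swimmer's tail, frozen tail, cold tail);
#  * "keyword_free" - tail phrases with no screening keyword, the texts a
#                     keyword rule can only route to manual review;
#  * "distractor"   - unrelated illness text without the word "tail".

#' Default free-text templates by class
#'
#' @return Named list of character vectors (`keyword`, `keyword_free`,
#'   `distractor`).
#' @export
default_report_templates <- function() {
  list(
    keyword = c(
      "Limp tail since yesterday",
      "Limber tail after a cold swim",
      "Swimmer's tail, very sorry for himself",
      "Cold tail after working in the rain",
      "Tail completely limp and droopy at the end",
      "Tail stiff at the base and limp further down",
      "Dead tail after swimming in the river",
      "Her tail just drops and won't lift"
    ),
    keyword_free = c(
      # "frozen tail" is a common owner phrasing yet carries no keyword stem
      "Frozen tail, hanging straight down",
      "She had a problem with her tail, she couldn't wag it for 5 days",
      "His tail was hanging low and he wouldn't move it",
      "Tail sore near the body, kept it tucked under",
      "Would not raise his tail and yelped when it was touched"
    ),
    distractor = c(
      "Diarrhoea for two days",
      "Lame on the front left leg after a long walk",
      "Ear infection, treated with drops from the vet",
      "Upset stomach after scavenging on the beach",
      "Cut pad, bandaged for a week"
    )
  )
}

#' Configuration for free-text report generation
#'
#' @param templates template list as in [default_report_templates()].
#' @param keyword_free_rate probability an affected dog's report is drawn
#'   from the keyword-free "tail" class instead of the keyword class
#'   (default 0.1; these reports are only recoverable by manual review).
#' @param distractor_rate probability an unaffected dog emits a distractor
#'   report (affected dogs additionally emit distractors at the same rate).
#' @param extra_report_prob probability an affected dog reports a second
#'   (and geometrically, further) episode, mirroring the minority of owners
#'   who reported repeat incidents.
#' @param vet_visit_rate probability a tail report involved a veterinary
#'   visit (default 11/53, the observed presentation fraction).
#' @param distractor_vet_rate vet-visit probability for distractor reports.
#' @return List of class `"report_config"`.
#' @export
report_config <- function(templates = default_report_templates(),
                          keyword_free_rate = 0.1,
                          distractor_rate = 0.05,
                          extra_report_prob = 0.2,
                          vet_visit_rate = 11 / 53,
                          distractor_vet_rate = 0.4) {
  if (!is.list(templates) ||
      !all(c("keyword", "keyword_free", "distractor") %in% names(templates))) {
    abort_arg("templates must list classes keyword, keyword_free, distractor")
  }
  if (any(lengths(templates[c("keyword", "keyword_free", "distractor")]) == 0L)) {
    abort_arg("empty template class")
  }
  for (p in list(keyword_free_rate, distractor_rate, extra_report_prob,
                 vet_visit_rate, distractor_vet_rate)) {
    if (!is_prob(p)) abort_arg("all report_config rates must be probabilities")
  }
  structure(as.list(environment()), class = "report_config")
}

#' Render owner free-text illness reports for a simulated cohort
#'
#' Every affected dog emits at least one tail report, drawn from the keyword
#' class or (with probability `keyword_free_rate`) the keyword-free class;
#' repeat episodes arise with probability `extra_report_prob` each.
#' Unaffected dogs emit unrelated distractor reports at `distractor_rate`.
#' Each row carries its ground-truth `template_class` so screening
#' sensitivity can be scored exactly.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param statuses result of [simulate_case_status()] (or its `$status`
#'   data frame).
#' @param config a [report_config()].
#' @param seed integer seed.
#' @return Data frame with columns `dog_id`, `report_date`, `text`,
#'   `vet_visit`, `template_class`.
#' @export
render_free_text_reports <- function(cohort, statuses, config = report_config(), seed) {
  if (!inherits(config, "report_config")) abort_arg("config must be a report_config()")
  status <- if (is.data.frame(statuses)) statuses else statuses$status
  if (!all(c("dog_id", "affected") %in% names(status))) {
    abort_arg("statuses must carry dog_id and affected")
  }
  idx <- match(cohort$dog_id, status$dog_id)
  if (anyNA(idx)) abort_arg("every cohort dog needs a simulated status")
  affected <- status$affected[idx]
  with_seed(seed, {
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      texts <- character(0); classes <- character(0)
      if (affected[i]) {
        n_rep <- 1L + stats::rgeom(1L, 1 - config$extra_report_prob)
        cls <- ifelse(stats::runif(n_rep) < config$keyword_free_rate,
                      "keyword_free", "keyword")
        texts <- vapply(cls, function(cl) sample(config$templates[[cl]], 1L), "")
        classes <- cls
      }
      if (stats::runif(1L) < config$distractor_rate) {
        texts <- c(texts, sample(config$templates$distractor, 1L))
        classes <- c(classes, "distractor")
      }
      if (!length(texts)) next
      base <- as.Date(cohort$birth_date[i]) + 240L
      is_tail <- classes != "distractor"
      rows[[i]] <- data.frame(
        dog_id = cohort$dog_id[i],
        report_date = base + sort(sample.int(900L, length(texts))),
        text = unname(texts),
        vet_visit = stats::runif(length(texts)) <
          ifelse(is_tail, config$vet_visit_rate, config$distractor_vet_rate),
        template_class = classes,
        stringsAsFactors = FALSE
      )
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) {
      return(data.frame(dog_id = character(0), report_date = as.Date(character(0)),
                        text = character(0), vet_visit = logical(0),
                        template_class = character(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
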