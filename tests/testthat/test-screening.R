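# Keyword screening of free-text reports: the matching rule, the review
# queue, incident accounting and the veterinary-presentation summary.

test_that("keyword rule matches tail plus stem, case-insensitively, as substrings", {
  res <- screen_report("Limber tail after a cold swim")
  expect_true(res$matched)
  expect_true(all(c("limber", "cold", "swim", "limb") %in% res$matched_keywords))
  expect_false(res$needs_review)

  res2 <- screen_report("She had a problem with her tail, she couldn't wag it for 5 days")
  expect_false(res2$matched)
  expect_true(res2$needs_review)

  res3 <- screen_report("Diarrhoea for two days")
  expect_false(res3$matched)
  expect_false(res3$needs_review)

  # stems hit inside longer words, and "tail" itself matches as a substring
  expect_true(screen_report("painful tailbase after swimming")$matched)
  expect_true(screen_report("TAIL LIMP AND DROOPY")$matched)

  res4 <- screen_report("")
  expect_false(res4$matched)
  expect_false(res4$needs_review)
})

test_that("matched implies non-empty keywords and review implies tail without keywords", {
  texts <- c("limp tail", "tail", "no problem at all", "tail held oddly",
             "swimmer's tail", "cold paws", "stiff tail base", "tail droopy")
  for (tx in texts) {
    r <- screen_report(tx)
    if (r$matched) expect_gt(length(r$matched_keywords), 0)
    if (r$needs_review) {
      expect_false(r$matched)
      expect_match(tx, "tail", ignore.case = TRUE)
    }
  }
})

test_that("adding a keyword can only promote review reports, never unmatch", {
  texts <- c("limp tail", "tail held low and sore", "wagging happily",
             "tail gone floppy", "dead tail after a swim")
  base <- default_keywords()
  wider <- c(base, "floppy")
  for (tx in texts) {
    before <- screen_report(tx, base)
    after <- screen_report(tx, wider)
    if (before$matched) expect_true(after$matched)
    if (after$needs_review) expect_true(before$needs_review)
  }
})

test_that("per-dog screening results are order-independent", {
  reports <- make_reports(
    dog_id = c("a", "b", "a", "c", "b", "d"),
    text = c("limp tail", "tail looks odd", "frozen tail", "lame leg",
             "cold tail", "swimmers tail"),
    vet_visit = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  s1 <- screen_cohort(reports)
  set.seed(3)
  s2 <- screen_cohort(reports[sample(nrow(reports)), ])
  expect_equal(s1$dogs, s2$dogs)
  expect_equal(s1$n_incidents, s2$n_incidents)
  expect_equal(s1$vet_missed$point, s2$vet_missed$point)
})

test_that("incident multiplicities and the missed-by-practice fraction are assembled correctly", {
  # one dog with 4 incidents, one with 3, five with 2, 36 with 1 -> 53/43;
  # 11 of the 43 dogs saw a veterinarian
  n_inc <- c(4, 3, rep(2, 5), rep(1, 36))
  dogs <- sprintf("dog%02d", seq_along(n_inc))
  rows <- do.call(rbind, lapply(seq_along(dogs), function(i) {
    make_reports(rep(dogs[i], n_inc[i]), rep("limp tail", n_inc[i]),
                 vet_visit = c(i <= 11, rep(FALSE, n_inc[i] - 1)),
                 report_date = as.Date("2013-01-01") + seq_len(n_inc[i]) * 20 + i)
  }))
  s <- screen_cohort(rows)
  expect_equal(s$n_incidents, 53L)
  expect_equal(s$n_dogs, 43L)
  expect_equal(as.integer(s$incident_multiplicity[c("1", "2", "3", "4")]),
               c(36L, 5L, 1L, 1L))
  expect_equal(s$vet_missed$k, 32L)
  expect_equal(s$vet_missed$n, 43L)
  expect_equal(round(100 * s$vet_missed$point), 74)
  expect_equal(round(100 * c(s$vet_missed$ci_low, s$vet_missed$ci_high), 1),
               c(58.8, 86.5))
})

test_that("same-day duplicate reports collapse into one incident", {
  d <- as.Date("2014-02-02")
  reports <- make_reports(c("a", "a", "a"), rep("limp tail", 3),
                          report_date = c(d, d, d + 30))
  expect_equal(screen_cohort(reports)$n_incidents, 2L)
})

test_that("manual-review overrides include and exclude dogs reproducibly", {
  reports <- make_reports(c("a", "b", "c"),
                          c("limp tail", "tail held low", "frozen tail"))
  ov <- data.frame(dog_id = c("b", "c"), decision = c("include", "exclude"),
                   stringsAsFactors = FALSE)
  s <- screen_cohort(reports, overrides = ov)
  expect_setequal(s$dogs$dog_id, c("a", "b"))
  expect_error(screen_cohort(reports, overrides = data.frame(dog_id = "a", decision = "maybe")),
               "unknown override")
})

test_that("empty report tables yield empty summaries", {
  s <- screen_cohort(make_reports(character(0), character(0)))
  expect_equal(s$n_dogs, 0L)
  expect_equal(s$n_incidents, 0L)
  expect_null(s$vet_missed)
})

test_that("screening recovers every keyword-class report and queues every keyword-free one", {
  ped <- generate_pedigree(300, 60, 80, 1, seed = 21)
  co <- generate_cohort(ped, seed = 22)
  st <- simulate_case_status(co, risk_params(sire_sd = 0), seed = 23)
  rep_tab <- render_free_text_reports(co, st, report_config(keyword_free_rate = 0.3),
                                      seed = 24)
  s <- screen_cohort(rep_tab)
  kw <- rep_tab$template_class == "keyword"
  kf <- rep_tab$template_class == "keyword_free"
  expect_true(all(s$results$matched[kw]))          # sensitivity 1 on keyword class
  expect_true(all(s$results$needs_review[kf]))     # keyword-free always reviewable
  expect_true(all(!s$results$matched[rep_tab$template_class == "distractor"]))
})
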