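# The synthetic cohort generator: pedigree allocation, covariate marginals,
# the latent disease model and determinism of every stage.

test_that("pedigree allocation conserves offspring and honours degenerate pools", {
  ped <- generate_pedigree(200, 40, 55, concentration = 1, seed = 1)
  expect_equal(nrow(ped), 200L)
  expect_false(anyDuplicated(ped$dog_id) > 0)
  expect_equal(sum(table(ped$sire_id)), 200L)
  expect_equal(sum(table(ped$dam_id)), 200L)
  expect_lte(length(unique(ped$sire_id)), 40L)
  expect_lte(length(unique(ped$dam_id)), 55L)

  one <- generate_pedigree(100, 1, 1, concentration = 0.3, seed = 2)
  expect_equal(length(unique(one$sire_id)), 1L)
  expect_equal(length(unique(one$dam_id)), 1L)

  expect_error(generate_pedigree(10, 0, 5, seed = 1), "n_sires")
  expect_error(generate_pedigree(10, 12, 5, seed = 1), "n_sires")
  expect_error(generate_pedigree(10, 5, 5, concentration = 0, seed = 1), "concentration")
})

test_that("large concentration approaches uniform parental contributions", {
  ped <- generate_pedigree(4000, 20, 20, concentration = 1e9, seed = 3)
  counts <- as.integer(table(ped$sire_id))
  # multinomial with equal cells: each count within 5 sd of 200
  expect_true(all(abs(counts - 200) < 5 * sqrt(4000 * (1 / 20) * (19 / 20))))
  # small concentration concentrates mass instead
  skew <- generate_pedigree(4000, 20, 20, concentration = 0.05, seed = 3)
  expect_gt(max(table(skew$sire_id)), max(counts))
})

test_that("cohort samples can show the illustrative {3,2,2,1x31} contribution pattern", {
  # a 38-dog random sample from a generated cohort pedigree can have sire
  # contributions of exactly one triple, two pairs and 31 singletons
  ped <- generate_pedigree(1000, 300, 300, concentration = 1, seed = 2026)
  set.seed(5)
  ids <- sample(ped$dog_id, 38)
  s <- contribution_statistic(ids, ped, "sire")
  expect_identical(sort(s$counts, decreasing = TRUE), c(3L, 2L, 2L, rep(1L, 31)))
  expect_equal(s$statistic, 48 / 38)
})

test_that("cohort covariate marginals track the configuration", {
  ped <- generate_pedigree(10000, 2000, 2500, 1, seed = 4)
  co <- generate_cohort(ped, cohort_config(p_swim = 0.85), seed = 5)
  se <- sqrt(0.85 * 0.15 / 10000)
  expect_lt(abs(mean(co$swims) - 0.85), 3 * se)
  expect_true(all(co$latitude >= 49 & co$latitude <= 61))
  expect_true(all(co$purpose %in% c("household_pet", "working", "gundog_and_pet", "other")))

  allwork <- generate_cohort(ped, cohort_config(
    purpose_probs = c(household_pet = 0, working = 1, gundog_and_pet = 0, other = 0)),
    seed = 6)
  expect_true(all(allwork$purpose == "working"))

  # default swimming prevalence sits near the questionnaire-control rate 68/86
  def <- generate_cohort(ped, seed = 7)
  p0 <- 68 / 86
  expect_lt(abs(mean(def$swims) - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("constant risk reproduces its intercept and swimming effect its odds ratio", {
  ped <- generate_pedigree(50000, 10000, 12000, 1, seed = 8)
  co <- generate_cohort(ped, seed = 9)
  flat <- risk_params(intercept = qlogis(0.1), beta_swim = 0, beta_work = 0,
                      beta_lat = 0, sire_sd = 0)
  st <- simulate_case_status(co, flat, seed = 10)
  expect_lt(abs(mean(st$status$affected) - 0.1), 3 * sqrt(0.1 * 0.9 / 50000))

  swim <- risk_params(intercept = qlogis(0.05), beta_swim = log(4.7),
                      beta_work = 0, beta_lat = 0, sire_sd = 0)
  st2 <- simulate_case_status(co, swim, seed = 11)
  aff <- st2$status$affected
  a <- sum(aff & co$swims); b <- sum(aff & !co$swims)
  c_ <- sum(!aff & co$swims); d <- sum(!aff & !co$swims)
  log_or <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_lt(abs(log_or - log(4.7)), 3 * se)
})

test_that("a single large fit recovers all three default effects", {
  ped <- generate_pedigree(30000, 6000, 7000, 1, seed = 12)
  co <- generate_cohort(ped, seed = 13)
  pars <- risk_params(sire_sd = 0)
  st <- simulate_case_status(co, pars, seed = 14)
  fit <- fit_logistic(as.integer(st$status$affected),
                      data.frame(swims = as.numeric(co$swims),
                                 working = as.numeric(co$purpose == "working"),
                                 latitude = co$latitude - pars$latitude_ref))
  truth <- c(pars$beta_swim, pars$beta_work, pars$beta_lat)
  est <- fit$coefficients[c("swims", "working", "latitude")]
  se <- fit$se[c("swims", "working", "latitude")]
  expect_true(all(abs(est - truth) < 4 * se))
})

test_that("free-text reports honour template classes and rates", {
  ped <- generate_pedigree(500, 100, 120, 1, seed = 15)
  co <- generate_cohort(ped, seed = 16)
  st <- simulate_case_status(co, risk_params(sire_sd = 0), seed = 17)
  reports <- render_free_text_reports(co, st, seed = 18)
  affected_ids <- st$status$dog_id[st$status$affected]
  tail_reports <- reports[reports$template_class != "distractor", ]
  expect_true(all(affected_ids %in% tail_reports$dog_id))   # every case reports
  expect_true(all(tail_reports$dog_id %in% affected_ids))   # only cases emit tail text
  expect_true(all(grepl("tail", tolower(tail_reports$text))))
  kw <- reports$template_class == "keyword"
  has_kw <- vapply(tolower(reports$text[kw]), function(tx) {
    any(vapply(default_keywords(), grepl, logical(1), x = tx, fixed = TRUE))
  }, logical(1))
  expect_true(all(has_kw))
  kf <- tolower(reports$text[reports$template_class == "keyword_free"])
  expect_true(all(!vapply(kf, function(tx) {
    any(vapply(default_keywords(), grepl, logical(1), x = tx, fixed = TRUE))
  }, logical(1))))

  # no affected dogs and no distractors -> no reports at all
  none <- simulate_case_status(co, risk_params(intercept = -50, beta_swim = 0,
                                               beta_work = 0, beta_lat = 0,
                                               sire_sd = 0), seed = 19)
  empty <- render_free_text_reports(co, none, report_config(distractor_rate = 0), seed = 20)
  expect_equal(nrow(empty), 0L)
})

test_that("questionnaire scores carry the configured pain/QoL correlation", {
  ped <- generate_pedigree(10000, 2000, 2500, 1, seed = 21)
  co <- generate_cohort(ped, seed = 22)
  all_aff <- simulate_case_status(co, risk_params(intercept = 50, beta_swim = 0,
                                                  beta_work = 0, beta_lat = 0,
                                                  sire_sd = 0), seed = 23)
  q <- generate_questionnaires(co, all_aff, seed = 24)
  keep <- !is.na(q$pain_score) & !is.na(q$qol_score)
  r <- pearson_correlation(q$pain_score[keep], q$qol_score[keep])
  se <- (1 - 0.72^2) / sqrt(sum(keep))
  expect_lt(abs(r - 0.72), 3 * se)
  expect_true(all(q$pain_score[keep] %in% 0:10))
  expect_true(all(q$qol_score[keep] %in% 0:10))
})

test_that("identical seeds reproduce byte-identical output tables", {
  run_once <- function(dir) {
    ped <- generate_pedigree(150, 30, 40, 1, seed = 100)
    co <- generate_cohort(ped, seed = 101)
    st <- simulate_case_status(co, risk_params(), seed = 102)
    rp <- render_free_text_reports(co, st, seed = 103)
    q <- generate_questionnaires(co, st, seed = 104)
    write_cohort_tables(dir, co, rp, q, st)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- run_once(d1); p2 <- run_once(d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     info = nm)
  }
  # and generators leave the session RNG untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_pedigree(10, 3, 3, 1, seed = 9))
  expect_identical(.Random.seed, before)
})
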