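# Synthetic tail-health questionnaire responses.
#
# Affected dogs report the five tail signs with configurable probabilities; a
# configurable fraction attribute their signs to an alternative cause (tail
# injury, impacted anal glands), which exercises the classifier's exclusion
# paths. Sign-free respondents answer "no" throughout. Pain and
# quality-of-life impact are owner scores on 0-10; they are generated from a
# latent bivariate normal whose correlation is calibrated so the *reported
# integer scores* (after rounding and clamping to the scale ends) carry the
# configured Pearson correlation, not an attenuated version of it.

#' Configuration of questionnaire response behaviour
#'
#' Probabilities are conditional on true affection status. `misattribution_rate`
#' is the fraction of affected, sign-reporting owners who attribute the signs
#' to an alternative cause; `control_sign_rate` is the fraction of unaffected
#' dogs whose owners nonetheless report tail signs (false alarms, mostly
#' attributed to another cause such as anal glands or lacking limpness).
#' The main route by which provisional controls are promoted to cases is
#' instead a genuinely affected dog whose free-text report carried no
#' screening keyword and so was missed at the screening stage.
#'
#' @param p_limp_end,p_limp_length,p_stiff_base,p_hair_on_end,p_painful
#'   per-sign reporting probabilities for affected dogs.
#' @param p_sign_unsure probability a reported "no" is softened to "unsure".
#' @param misattribution_rate see above.
#' @param control_sign_rate,control_limp_given_sign,control_attribution_rate
#'   sign behaviour of unaffected dogs.
#' @param pain_mean,pain_sd,qol_mean,qol_sd score distribution parameters on
#'   the 0-10 scale.
#' @param pain_qol_correlation target Pearson correlation of the reported
#'   integer pain and quality-of-life scores (default 0.72).
#' @param p_pain_reported_yes,p_pain_reported_unsure marginal probabilities of
#'   the categorical "was it painful" answer; generated independently of the
#'   numeric score, so the inconsistent no-with-nonzero-score answers real
#'   owners give arise naturally and are retained.
#' @param duration_probs named probabilities over duration categories
#'   (defaults give a mean recoded duration near 3.5 days).
#' @param episode_probs probabilities for 1, 2, 3, 4 reported episodes.
#' @param precursor_probs named list; per precursor, probabilities of
#'   yes/no/unsure for sign-reporting dogs.
#' @return List of class `"questionnaire_config"`.
#' @export
questionnaire_config <- function(p_limp_end = 0.85, p_limp_length = 0.4,
                                 p_stiff_base = 0.5, p_hair_on_end = 0.15,
                                 p_painful = 0.6, p_sign_unsure = 0.05,
                                 misattribution_rate = 0.05,
                                 control_sign_rate = 5 / 93,
                                 control_limp_given_sign = 0.4,
                                 control_attribution_rate = 0.6,
                                 pain_mean = 6, pain_sd = 2.6,
                                 qol_mean = 4.1, qol_sd = 3,
                                 pain_qol_correlation = 0.72,
                                 p_pain_reported_yes = 0.6,
                                 p_pain_reported_unsure = 0.08,
                                 duration_probs = c("a few hours" = 0.10,
                                                    "1 day" = 0.15,
                                                    "2 days" = 0.15,
                                                    "a few days" = 0.35,
                                                    "a week or more" = 0.25),
                                 episode_probs = c(0.58, 0.21, 0.13, 0.08),
                                 precursor_probs = list(
                                   swimming = c(yes = 0.75, no = 0.25, unsure = 0),
                                   cold_weather = c(yes = 0.5, no = 0.5, unsure = 0),
                                   vigorous_exercise = c(yes = 0.47, no = 0.47, unsure = 0.06),
                                   wet_weather = c(yes = 0.29, no = 0.68, unsure = 0.03),
                                   confinement = c(yes = 0.15, no = 0.82, unsure = 0.03)
                                 )) {
  rates <- c(p_limp_end, p_limp_length, p_stiff_base, p_hair_on_end, p_painful,
             p_sign_unsure, misattribution_rate, control_sign_rate,
             control_limp_given_sign, control_attribution_rate,
             p_pain_reported_yes, p_pain_reported_unsure)
  if (!all(vapply(rates, is_prob, logical(1)))) {
    abort_arg("all questionnaire rates must be probabilities in [0, 1]")
  }
  if (!is.numeric(pain_qol_correlation) || abs(pain_qol_correlation) >= 1) {
    abort_arg("pain_qol_correlation must lie in (-1, 1)")
  }
  if (abs(sum(duration_probs) - 1) > 1e-8 || is.null(names(duration_probs))) {
    abort_arg("duration_probs must be named and sum to 1")
  }
  if (abs(sum(episode_probs) - 1) > 1e-8) abort_arg("episode_probs must sum to 1")
  for (pp in precursor_probs) {
    if (abs(sum(pp) - 1) > 1e-8) abort_arg("each precursor probability triple must sum to 1")
  }
  structure(as.list(environment()), class = "questionnaire_config")
}

# expected Pearson correlation of round-and-clamp transformed scores when the
# latent normals have correlation rho, by 2-D quadrature on a normal grid
rounded_score_correlation <- function(rho, mean1, sd1, mean2, sd2, lo = 0, hi = 10) {
  z <- seq(-6, 6, by = 0.06)
  w <- stats::dnorm(z); w <- w / sum(w)
  clamp <- function(v) pmin(pmax(round(v), lo), hi)
  x <- clamp(mean1 + sd1 * z)                       # depends on z1 only
  Ex <- sum(w * x); Ex2 <- sum(w * x^2)
  z2 <- outer(rho * z, sqrt(1 - rho^2) * z, "+")    # z2 | z1 grid
  y <- clamp(mean2 + sd2 * z2)
  wy <- as.vector(y %*% w)                          # E[Y | z1]
  wy2 <- as.vector(y^2 %*% w)
  Ey <- sum(w * wy); Ey2 <- sum(w * wy2)
  Exy <- sum(w * x * wy)
  (Exy - Ex * Ey) / sqrt((Ex2 - Ex^2) * (Ey2 - Ey^2))
}

# latent correlation that yields the target correlation after discretisation
calibrate_latent_correlation <- function(target, mean1, sd1, mean2, sd2) {
  if (target == 0) return(0)
  s <- sign(target); t <- abs(target)
  f <- function(r) rounded_score_correlation(r, mean1, sd1, mean2, sd2) - t
  if (f(0.9999) < 0) return(s * 0.9999) # target unreachable after clamping
  s * stats::uniroot(f, c(0, 0.9999), tol = 1e-6)$root
}

sample_tri <- function(n, p3) {
  # p3 = c(yes, no, unsure)
  sample(c("yes", "no", "unsure"), n, replace = TRUE, prob = p3)
}

#' Generate questionnaire responses for a simulated cohort
#'
#' One response per dog. Affected dogs report signs per the configured
#' probabilities; a `misattribution_rate` fraction of sign-reporting affected
#' dogs attribute the signs to an alternative cause. Unaffected dogs report
#' signs at `control_sign_rate`. Pain and quality-of-life scores (and the
#' categorical pain answer, duration category, episode count and precursor
#' exposures) are emitted for every sign-reporting respondent.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param statuses result of [simulate_case_status()] or its `$status`.
#' @param config a [questionnaire_config()].
#' @param seed integer seed.
#' @return Data frame with one row per dog: the five `sign_*` columns
#'   (`yes`/`no`/`unsure`), `attribution`, `attribution_text`, five
#'   `precursor_*` columns, `pain_score` and `qol_score` (integer 0-10 or
#'   `NA`), `pain_reported`, `n_episodes`, `duration_category`, `swims_ever`.
#' @export
generate_questionnaires <- function(cohort, statuses, config = questionnaire_config(), seed) {
  if (!inherits(config, "questionnaire_config")) abort_arg("config must be a questionnaire_config()")
  status <- if (is.data.frame(statuses)) statuses else statuses$status
  idx <- match(cohort$dog_id, status$dog_id)
  if (anyNA(idx)) abort_arg("every cohort dog needs a simulated status")
  affected <- status$affected[idx]
  n <- nrow(cohort)
  with_seed(seed, {
    soften <- function(ans) {
      # a slice of "no" answers becomes "unsure"
      flip <- ans == "no" & stats::runif(length(ans)) < config$p_sign_unsure
      ans[flip] <- "unsure"
      ans
    }
    yn <- function(p, gate) ifelse(gate & stats::runif(n) < p, "yes", "no")

    sign_limp_end <- yn(config$p_limp_end, affected)
    sign_limp_length <- yn(config$p_limp_length, affected)
    sign_stiff_base <- yn(config$p_stiff_base, affected)
    sign_hair_on_end <- yn(config$p_hair_on_end, affected)
    sign_painful <- yn(config$p_painful, affected)

    # unaffected dogs occasionally report signs (the promoted-control route)
    ctl_sign <- !affected & stats::runif(n) < config$control_sign_rate
    ctl_limp <- ctl_sign & stats::runif(n) < config$control_limp_given_sign
    sign_limp_end[ctl_limp] <- "yes"
    sign_stiff_base[ctl_sign & !ctl_limp] <- "yes"

    for (v in c("sign_limp_end", "sign_limp_length", "sign_stiff_base",
                "sign_hair_on_end", "sign_painful")) {
      assign(v, soften(get(v)))
    }

    any_sign <- sign_limp_end == "yes" | sign_limp_length == "yes" |
      sign_stiff_base == "yes" | sign_hair_on_end == "yes" | sign_painful == "yes"

    attribution <- rep("none", n)
    attribution_text <- rep("", n)
    mis <- affected & any_sign & stats::runif(n) < config$misattribution_rate
    attribution[mis] <- sample(c("injury", "anal_glands", "other_cause"),
                               sum(mis), replace = TRUE, prob = c(0.5, 0.3, 0.2))
    ctl_attr <- ctl_sign & stats::runif(n) < config$control_attribution_rate
    attribution[ctl_attr] <- "anal_glands"
    attribution_text[attribution == "anal_glands"] <-
      "suspected the signs were related to impacted anal glands"
    attribution_text[attribution == "injury"] <- "caught the tail in a door"
    attribution_text[attribution == "other_cause"] <- "put it down to old sprain"

    # pain / quality-of-life scores for sign-reporting respondents
    rho <- calibrate_latent_correlation(config$pain_qol_correlation,
                                        config$pain_mean, config$pain_sd,
                                        config$qol_mean, config$qol_sd)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    pain_score <- pmin(pmax(round(config$pain_mean + config$pain_sd * z1), 0L), 10L)
    qol_score <- pmin(pmax(round(config$qol_mean + config$qol_sd * z2), 0L), 10L)
    pain_score[!any_sign] <- NA_integer_
    qol_score[!any_sign] <- NA_integer_

    p_yes <- config$p_pain_reported_yes; p_uns <- config$p_pain_reported_unsure
    pain_reported <- ifelse(any_sign,
                            sample(c("yes", "no", "unsure"), n, replace = TRUE,
                                   prob = c(p_yes, 1 - p_yes - p_uns, p_uns)),
                            "no")

    duration_category <- ifelse(any_sign,
                                sample(names(config$duration_probs), n, replace = TRUE,
                                       prob = config$duration_probs),
                                NA_character_)
    n_episodes <- ifelse(any_sign,
                         sample(seq_along(config$episode_probs), n, replace = TRUE,
                                prob = config$episode_probs),
                         0L)

    out <- data.frame(dog_id = cohort$dog_id,
                      sign_limp_end = sign_limp_end,
                      sign_limp_length = sign_limp_length,
                      sign_stiff_base = sign_stiff_base,
                      sign_hair_on_end = sign_hair_on_end,
                      sign_painful = sign_painful,
                      attribution = attribution,
                      attribution_text = attribution_text,
                      stringsAsFactors = FALSE)
    for (pc in names(config$precursor_probs)) {
      ans <- sample_tri(n, config$precursor_probs[[pc]])
      ans[!any_sign] <- "no"
      out[[paste0("precursor_", pc)]] <- ans
    }
    out$pain_score <- pain_score
    out$qol_score <- qol_score
    out$pain_reported <- pain_reported
    out$n_episodes <- as.integer(n_episodes)
    out$duration_category <- duration_category
    out$swims_ever <- cohort$swims
    out
  })
}
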