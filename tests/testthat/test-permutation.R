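# Parental-contribution statistic and the permutation test: hand-computed
# values, structural bounds, oracle agreement and power.

test_that("the contribution statistic reproduces the illustrative {3,2,2,1x31} pattern", {
  ped <- ped_3_2_2_31()
  s <- contribution_statistic(ped$dog_id, ped, "sire", "offspring_weighted")
  expect_equal(sort(s$counts, decreasing = TRUE), c(3L, 2L, 2L, rep(1L, 31)))
  expect_equal(s$n_dogs, 38L)
  expect_equal(s$n_parents, 34L)
  expect_equal(s$statistic, 48 / 38)     # (9 + 4 + 4 + 31) / 38
  expect_equal(s$plain_mean, 38 / 34)
})

test_that("all-distinct parents give statistic 1 and a single parent gives n", {
  ped <- make_ped(letters[1:6], paste0("s", 1:6))
  expect_equal(contribution_statistic(ped$dog_id, ped, "sire")$statistic, 1)
  expect_equal(contribution_statistic(ped$dog_id, ped, "sire", "plain_mean")$statistic, 1)
  ped1 <- make_ped(letters[1:6], rep("s1", 6))
  expect_equal(contribution_statistic(ped1$dog_id, ped1, "sire")$statistic, 6)
  expect_equal(contribution_statistic(ped1$dog_id, ped1, "sire", "plain_mean")$statistic, 6)
})

test_that("the statistic stays within [1, sample size] on random pedigrees", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    ped <- generate_pedigree(n, sample.int(n, 1), sample.int(n, 1),
                             concentration = runif(1, 0.05, 5), seed = i)
    ids <- sample(ped$dog_id, sample(2:n, 1))
    for (w in c("offspring_weighted", "plain_mean")) {
      s <- contribution_statistic(ids, ped, sample(c("sire", "dam"), 1), w)
      expect_gte(s$statistic, 1)
      expect_lte(s$statistic, s$n_dogs)
    }
  }
})

test_that("dogs with unknown parents are dropped with a recorded count", {
  ped <- make_ped(letters[1:5], c("s1", "s1", NA, "s2", ""))
  expect_warning(s <- contribution_statistic(letters[1:5], validate_pedigree(ped), "sire"),
                 "unknown sire")
  expect_equal(s$n_excluded, 2L)
  expect_equal(s$n_dogs, 3L)
})

test_that("relabelling dogs and parents leaves statistics and p-values unchanged", {
  ped <- generate_pedigree(60, 12, 15, 0.5, seed = 77)
  cases <- ped$dog_id[1:15]
  map_dog <- setNames(sprintf("X%03d", seq_len(nrow(ped))), ped$dog_id)
  map_sire <- setNames(sprintf("Y%03d", seq_along(unique(ped$sire_id))),
                       unique(ped$sire_id))
  ped2 <- data.frame(dog_id = unname(map_dog[ped$dog_id]),
                     sire_id = unname(map_sire[ped$sire_id]),
                     dam_id = ped$dam_id, stringsAsFactors = FALSE)
  s1 <- contribution_statistic(cases, ped, "sire")
  s2 <- contribution_statistic(unname(map_dog[cases]), ped2, "sire")
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(sort(s1$counts), sort(s2$counts))
  r1 <- permutation_test(cases, ped$dog_id, ped, "sire", n_perm = 300, seed = 5)
  r2 <- permutation_test(unname(map_dog[cases]), map_dog[ped$dog_id], ped2, "sire",
                         n_perm = 300, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$null_values, r2$null_values)
})

test_that("sampling the whole cohort is degenerate with p = 1", {
  ped <- generate_pedigree(20, 5, 6, 0.5, seed = 3)
  r <- permutation_test(ped$dog_id, ped$dog_id, ped, "sire", n_perm = 50, seed = 1)
  expect_true(all(r$null_values == r$observed$statistic))
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
})

test_that("identical seeds give identical permutation results", {
  ped <- generate_pedigree(80, 16, 20, 0.5, seed = 4)
  cases <- ped$dog_id[1:12]
  r1 <- permutation_test(cases, ped$dog_id, ped, "dam", n_perm = 500, seed = 42)
  r2 <- permutation_test(cases, ped$dog_id, ped, "dam", n_perm = 500, seed = 42)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(permutation_test(c(cases, "ghost"), ped$dog_id, ped, "sire",
                                n_perm = 10, seed = 1),
               "subset")
})

test_that("exhaustive enumeration covers C(n, k) subsets and bounds refuse", {
  ped <- make_ped(letters[1:5], c("s1", "s1", "s2", "s2", "s3"))
  ex <- exhaustive_null(2, ped$dog_id, ped, "sire")
  expect_equal(ex$n_subsets, 10L)
  expect_equal(length(ex$values), 10L)
  one <- exhaustive_null(4, letters[1:4], make_ped(letters[1:4], paste0("s", 1:4)), "sire")
  expect_equal(one$n_subsets, 1L)
  expect_equal(one$tail_p(one$values), 1)
  expect_error(exhaustive_null(10, sprintf("d%d", 1:30),
                               generate_pedigree(30, 5, 5, 1, seed = 1),
                               max_subsets = 100),
               "refusing")
})

test_that("Monte-Carlo tail probabilities converge to the exhaustive oracle", {
  # 6 dogs, two sires with 3 offspring each; cases = one sire's litter
  ped <- make_ped(letters[1:6], rep(c("s1", "s2"), each = 3))
  cases <- letters[1:3]
  obs <- contribution_statistic(cases, ped, "sire")$statistic
  expect_equal(obs, 3)
  ex <- exhaustive_null(3, ped$dog_id, ped, "sire")
  p_exact <- ex$tail_p(obs)
  expect_equal(p_exact, 2 / 20)  # only the two single-litter subsets reach 3
  mc <- permutation_test(cases, ped$dog_id, ped, "sire", n_perm = 10000, seed = 9)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$p_value - p_exact), 3 * se + 1 / 10001)
})

test_that("rejection rate grows with the sire effect and exceeds the nominal level", {
  ped <- generate_pedigree(600, 120, 150, 1, seed = 42)
  co <- generate_cohort(ped, seed = 43)
  rej <- vapply(c(0.5, 1.5, 2.5), function(ss) {
    pars <- risk_params(intercept = qlogis(0.008), beta_swim = 0, beta_work = 0,
                        beta_lat = 0, sire_sd = ss)
    mean(vapply(1:500, function(r) {
      st <- simulate_case_status(co, pars, seed = 5000 + r)
      ids <- st$status$dog_id[st$status$affected]
      if (length(ids) < 2) return(NA)
      permutation_test(ids, co$dog_id, ped, "sire", n_perm = 99,
                       seed = r)$p_value <= 0.05
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rej) > 0))   # monotone in sire_sd
  expect_gt(rej[3], 0.5)            # ~38-case samples: power well above half
  expect_gt(rej[2], 0.05)           # above the nominal level already mid-grid
})

test_that("significance is declared exactly when the observed statistic clears the 97.5th centile", {
  ped <- generate_pedigree(200, 40, 50, 0.5, seed = 6)
  co <- generate_cohort(ped, seed = 7)
  for (ss in c(0, 3)) {
    st <- simulate_case_status(co, risk_params(intercept = qlogis(0.05),
                                               sire_sd = ss), seed = 8 + ss)
    ids <- st$status$dog_id[st$status$affected]
    r <- permutation_test(ids, co$dog_id, ped, "sire", n_perm = 400, seed = 9)
    expect_identical(r$significant, r$observed$statistic > r$pct_97_5)
    expect_lte(r$pct_2_5, r$pct_97_5)
    expect_gte(r$p_value, 1 / (r$n_perm + 1))
  }
})
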