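# Permutation test of parental-contribution clustering.
#
# For a sampled set of dogs, group them by sire (or dam) and summarise how
# concentrated the parental contributions are. With per-parent offspring
# counts c_1..c_k (sum = n sampled dogs):
#
#   offspring_weighted:  sum(c_i^2) / sum(c_i)   - each parent weighted by its
#                        own contribution, the reading under which parents of
#                        several sampled offspring are "weighted and averaged";
#   plain_mean:          n / k                   - mean offspring per
#                        contributing parent.
#
# Both equal 1 when all parents are distinct and n when a single parent
# contributed every sampled dog. The null distribution is built from repeated
# simple random samples of the same size drawn from the whole cohort.

statistic_from_counts <- function(counts, weighting) {
  switch(weighting,
         offspring_weighted = sum(counts^2) / sum(counts),
         plain_mean = sum(counts) / length(counts),
         abort_arg("unknown weighting '%s'", weighting))
}

#' Parental-contribution statistic of a dog sample
#'
#' @param dog_ids character vector (a set) of sampled dog ids.
#' @param pedigree pedigree data frame (`dog_id`, `sire_id`, `dam_id`).
#' @param parent_axis `"sire"` or `"dam"`.
#' @param weighting `"offspring_weighted"` (default) or `"plain_mean"`.
#' @return Object of class `"contribution_summary"`: list with `parent_axis`,
#'   `weighting`, `counts` (offspring per contributing parent, decreasing),
#'   `n_parents`, `n_dogs`, `statistic`, `plain_mean`, `n_excluded`
#'   (dogs dropped for an unknown parent on the chosen axis).
#' @examples
#' ped <- generate_pedigree(38, 34, 34, concentration = 0.8, seed = 7)
#' contribution_statistic(ped$dog_id[1:10], ped, "sire")
#' @export
contribution_statistic <- function(dog_ids, pedigree,
                                   parent_axis = c("sire", "dam"),
                                   weighting = c("offspring_weighted", "plain_mean")) {
  parent_axis <- match.arg(parent_axis)
  weighting <- match.arg(weighting)
  pedigree <- validate_pedigree(pedigree)
  dog_ids <- unique(dog_ids)
  idx <- match(dog_ids, pedigree$dog_id)
  if (anyNA(idx)) {
    abort_arg("dog(s) absent from pedigree: %s",
              paste(dog_ids[is.na(idx)], collapse = ", "))
  }
  parent <- pedigree[[paste0(parent_axis, "_id")]][idx]
  n_excluded <- sum(is.na(parent))
  if (n_excluded > 0) {
    warning(n_excluded, " dog(s) with unknown ", parent_axis,
            " excluded from the contribution statistic", call. = FALSE)
    parent <- parent[!is.na(parent)]
  }
  if (!length(parent)) abort_arg("no dogs with a known %s", parent_axis)
  counts <- sort(as.integer(table(parent)), decreasing = TRUE)
  structure(
    list(parent_axis = parent_axis, weighting = weighting, counts = counts,
         n_parents = length(counts), n_dogs = sum(counts),
         statistic = statistic_from_counts(counts, weighting),
         plain_mean = statistic_from_counts(counts, "plain_mean"),
         n_excluded = n_excluded),
    class = "contribution_summary"
  )
}

#' @export
print.contribution_summary <- function(x, ...) {
  cat(sprintf("%s contributions for %d dogs: %d parents, statistic = %.4f (%s), plain mean = %.4f\n",
              x$parent_axis, x$n_dogs, x$n_parents, x$statistic, x$weighting,
              x$plain_mean))
  invisible(x)
}

#' Permutation test of case clustering by sire or dam
#'
#' Compares the observed contribution statistic of the case set with its
#' distribution over `n_perm` simple random samples (without replacement) of
#' the same size drawn from the full cohort. The upper-tail p-value uses the
#' add-one rule `p = (1 + #(null >= observed)) / (n_perm + 1)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`. Familial clustering is called
#' significant when the observed statistic exceeds the 97.5th percentile of
#' the null sample.
#'
#' Dogs with an unknown parent on the chosen axis are dropped, from the case
#' set and from the sampling frame alike, with the count recorded.
#'
#' @param case_ids ids of the case dogs (must be a subset of `cohort_ids`).
#' @param cohort_ids ids of the full cohort sampled under the null.
#' @param pedigree pedigree data frame.
#' @param parent_axis `"sire"` or `"dam"`.
#' @param n_perm number of permutation samples (default 10000).
#' @param seed integer seed.
#' @param weighting statistic weighting, see [contribution_statistic()].
#' @return Object of class `"permutation_result"`: list with `observed`
#'   (a [contribution_statistic()] summary), `null_values`, `pct_2_5`,
#'   `pct_97_5`, `p_value`, `significant`, `n_perm`, `seed`, `parent_axis`,
#'   `weighting`, `n_excluded`.
#' @export
permutation_test <- function(case_ids, cohort_ids, pedigree,
                             parent_axis = c("sire", "dam"),
                             n_perm = 10000, seed,
                             weighting = c("offspring_weighted", "plain_mean")) {
  parent_axis <- match.arg(parent_axis)
  weighting <- match.arg(weighting)
  if (!is_count(n_perm) || n_perm < 1) abort_arg("n_perm must be a positive integer")
  case_ids <- unique(case_ids); cohort_ids <- unique(cohort_ids)
  if (!all(case_ids %in% cohort_ids)) abort_arg("case_ids must be a subset of cohort_ids")
  pedigree <- validate_pedigree(pedigree)
  col <- paste0(parent_axis, "_id")
  parent_all <- stats::setNames(pedigree[[col]], pedigree$dog_id)[cohort_ids]
  if (anyNA(match(cohort_ids, pedigree$dog_id))) {
    abort_arg("cohort dog(s) absent from pedigree")
  }
  known <- !is.na(parent_all)
  n_excluded <- sum(!known)
  if (n_excluded > 0) {
    warning(n_excluded, " cohort dog(s) with unknown ", parent_axis,
            " dropped from the sampling frame", call. = FALSE)
  }
  frame_ids <- cohort_ids[known]
  case_ids <- case_ids[case_ids %in% frame_ids]
  m <- length(case_ids)
  if (m < 1) abort_arg("no case dogs with a known %s", parent_axis)
  if (m > length(frame_ids)) abort_arg("case set larger than the sampling frame")
  observed <- contribution_statistic(case_ids, pedigree, parent_axis, weighting)
  parent_idx <- as.integer(factor(parent_all[known]))
  n_parents <- max(parent_idx)
  N <- length(frame_ids)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      cnt <- tabulate(parent_idx[sample.int(N, m)], nbins = n_parents)
      statistic_from_counts(cnt[cnt > 0L], weighting)
    }, numeric(1))
  })
  q <- stats::quantile(null_values, c(0.025, 0.975), names = FALSE, type = 7)
  p <- (1 + sum(null_values >= observed$statistic)) / (n_perm + 1)
  structure(
    list(observed = observed, null_values = null_values,
         pct_2_5 = q[1], pct_97_5 = q[2], p_value = p,
         significant = observed$statistic > q[2],
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         parent_axis = parent_axis, weighting = weighting,
         n_excluded = n_excluded),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s-contribution permutation test (%s, %d samples, seed %d)\n",
              x$parent_axis, x$weighting, x$n_perm, x$seed))
  cat(sprintf("observed %.4f vs null band [%.4f, %.4f]; upper-tail p = %.4g\n",
              x$observed$statistic, x$pct_2_5, x$pct_97_5, x$p_value))
  cat(if (x$significant) "observed statistic lies beyond the 97.5th centile: significant familial clustering\n"
      else "no evidence of clustering beyond the null band\n")
  invisible(x)
}

#' Exhaustive null distribution of the contribution statistic
#'
#' Enumerates every subset of `case_size` dogs from `cohort_ids` and computes
#' the statistic for each - the brute-force oracle against which the
#' Monte-Carlo sampler is validated. Refuses when the number of subsets
#' exceeds `max_subsets`.
#'
#' @param case_size sample size.
#' @param cohort_ids cohort ids (all must have a known parent on the axis).
#' @param pedigree pedigree data frame.
#' @param parent_axis `"sire"` or `"dam"`.
#' @param weighting statistic weighting.
#' @param max_subsets enumeration cap (default 1e6).
#' @return List with `values` (one statistic per subset), `n_subsets`, and
#'   `tail_p(observed)`, a function giving the exact upper-tail probability
#'   `P(null >= observed)`.
#' @export
exhaustive_null <- function(case_size, cohort_ids, pedigree,
                            parent_axis = c("sire", "dam"),
                            weighting = c("offspring_weighted", "plain_mean"),
                            max_subsets = 1e6) {
  parent_axis <- match.arg(parent_axis)
  weighting <- match.arg(weighting)
  pedigree <- validate_pedigree(pedigree)
  cohort_ids <- unique(cohort_ids)
  N <- length(cohort_ids)
  if (!is_count(case_size) || case_size < 1 || case_size > N) {
    abort_arg("case_size must be an integer in [1, length(cohort_ids)]")
  }
  n_subsets <- choose(N, case_size)
  if (n_subsets > max_subsets) {
    abort_arg("refusing to enumerate %.3g subsets (cap %.3g)", n_subsets, max_subsets)
  }
  parent <- stats::setNames(pedigree[[paste0(parent_axis, "_id")]],
                            pedigree$dog_id)[cohort_ids]
  if (anyNA(parent)) abort_arg("all cohort dogs must have a known %s", parent_axis)
  parent_idx <- as.integer(factor(parent))
  n_parents <- max(parent_idx)
  values <- utils::combn(N, case_size, FUN = function(sel) {
    cnt <- tabulate(parent_idx[sel], nbins = n_parents)
    statistic_from_counts(cnt[cnt > 0L], weighting)
  })
  list(values = values, n_subsets = as.integer(n_subsets),
       tail_p = function(observed) mean(values >= observed))
}
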