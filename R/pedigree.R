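# Single-generation pedigree simulation.
#
# Parents are not themselves cohort members: each cohort dog has one sire and
# one dam drawn from fixed parent pools. Offspring are allocated by a
# Dirichlet-multinomial scheme so that one concentration parameter spans the
# whole range from near-uniform parental contributions (large concentration)
# to a few dominant parents (small concentration).

#' Generate a single-generation pedigree
#'
#' Each of `n_dogs` cohort members is independently assigned a sire from a
#' pool of `n_sires` and a dam from a pool of `n_dams`. Assignment
#' probabilities are drawn once per parent pool from a symmetric Dirichlet
#' with the given `concentration`, so offspring counts per parent follow a
#' Dirichlet-multinomial: small concentrations produce skewed contribution
#' patterns (a few popular sires), large concentrations approach uniform
#' allocation.
#'
#' @param n_dogs number of cohort dogs (>= 1).
#' @param n_sires,n_dams sizes of the sire and dam pools (1 <= pool <= n_dogs).
#' @param concentration positive Dirichlet concentration; default 1 (flat
#'   Dirichlet, moderately skewed contributions).
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#' @return Object of class `"dog_pedigree"`: a data frame with columns
#'   `dog_id`, `sire_id`, `dam_id`.
#' @examples
#' ped <- generate_pedigree(38, 34, 34, concentration = 0.5, seed = 1)
#' table(table(ped$sire_id))
#' @export
generate_pedigree <- function(n_dogs, n_sires, n_dams, concentration = 1, seed) {
  if (!is_count(n_dogs) || n_dogs < 1) abort_arg("n_dogs must be a positive integer")
  if (!is_count(n_sires) || n_sires < 1 || n_sires > n_dogs) {
    abort_arg("n_sires must be an integer in [1, n_dogs]")
  }
  if (!is_count(n_dams) || n_dams < 1 || n_dams > n_dogs) {
    abort_arg("n_dams must be an integer in [1, n_dogs]")
  }
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0) {
    abort_arg("concentration must be a positive finite number")
  }
  with_seed(seed, {
    p_sire <- dirichlet_weights(n_sires, concentration)
    p_dam <- dirichlet_weights(n_dams, concentration)
    ped <- data.frame(
      dog_id = sprintf("D%05d", seq_len(n_dogs)),
      sire_id = sprintf("S%04d", sample.int(n_sires, n_dogs, replace = TRUE, prob = p_sire)),
      dam_id = sprintf("M%04d", sample.int(n_dams, n_dogs, replace = TRUE, prob = p_dam)),
      stringsAsFactors = FALSE
    )
    class(ped) <- c("dog_pedigree", "data.frame")
    ped
  })
}

# one draw from a symmetric Dirichlet via normalised gammas; guards against
# an all-zero draw at very small concentrations
dirichlet_weights <- function(k, concentration) {
  w <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(w) == 0) w <- rep(1, k)
  w / sum(w)
}

#' Validate a pedigree table
#'
#' Checks the structural invariants used throughout the package: unique dog
#' ids, no dog is its own sire or dam, and parent columns present. Unknown
#' parents are encoded as `NA` or the empty string.
#'
#' @param pedigree data frame with columns `dog_id`, `sire_id`, `dam_id`.
#' @return The pedigree, invisibly, with empty-string parents normalised to
#'   `NA`; stops on violation.
#' @export
validate_pedigree <- function(pedigree) {
  req <- c("dog_id", "sire_id", "dam_id")
  missing_cols <- setdiff(req, names(pedigree))
  if (length(missing_cols)) abort_arg("pedigree lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(pedigree$dog_id)) abort_arg("duplicate dog_id in pedigree")
  for (col in c("sire_id", "dam_id")) {
    v <- pedigree[[col]]
    v[!is.na(v) & v == ""] <- NA
    pedigree[[col]] <- v
    self <- !is.na(v) & v == pedigree$dog_id
    if (any(self)) abort_arg("dog(s) listed as their own %s: %s", sub("_id$", "", col),
                             paste(pedigree$dog_id[self], collapse = ", "))
  }
  invisible(pedigree)
}
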