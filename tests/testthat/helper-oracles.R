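# Independent brute-force oracles used to validate the exact 2x2 machinery
# and the permutation sampler. These deliberately avoid the package's
# log-space noncentral hypergeometric code path: probabilities come from
# plain choose() products, maximisation from a coarse grid refined by
# stats::optimize() on the raw likelihood.

# conditional probabilities of every table with the given margins at odds
# ratio psi; m/n = case/control totals, k = exposed total
bf_probs <- function(m, n, k, psi) {
  x <- max(0, k - n):min(k, m)
  w <- choose(m, x) * choose(n, k - x) * psi^x
  list(x = x, p = w / sum(w))
}

bf_fisher_two_sided <- function(a, b, c, d) {
  pr <- bf_probs(a + b, c + d, a + c, 1)
  pobs <- pr$p[pr$x == a]
  sum(pr$p[pr$p <= pobs * (1 + 1e-07)])
}

# conditional MLE by maximising the brute-force likelihood on a log-psi grid,
# refined with optimize(); returns 0/Inf on the support boundary
bf_cmle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  if (length(x) == 1) return(NaN)
  if (a <= min(x)) return(0)
  if (a >= max(x)) return(Inf)
  loglik <- function(lp) {
    lw <- log(choose(m, x) * choose(n, k - x)) + x * lp
    mx <- max(lw)
    a * lp - (mx + log(sum(exp(lw - mx))))
  }
  grid <- seq(-30, 30, by = 0.25)
  i <- which.max(vapply(grid, loglik, numeric(1)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  exp(stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum)
}

# small hand-built pedigree
make_ped <- function(dog_id, sire_id, dam_id = sire_id) {
  data.frame(dog_id = dog_id, sire_id = sire_id, dam_id = dam_id,
             stringsAsFactors = FALSE)
}

# a pedigree whose sire contribution multiset is exactly {3, 2, 2, 1 x 31}
ped_3_2_2_31 <- function() {
  sires <- c(rep("sA", 3), rep("sB", 2), rep("sC", 2), sprintf("s%02d", 1:31))
  make_ped(sprintf("d%02d", seq_along(sires)), sires)
}

# minimal illness-report table builder
make_reports <- function(dog_id, text, vet_visit = FALSE,
                         report_date = as.Date("2014-06-01") + seq_along(dog_id)) {
  data.frame(dog_id = dog_id, report_date = report_date, text = text,
             vet_visit = rep(vet_visit, length.out = length(dog_id)),
             stringsAsFactors = FALSE)
}

# questionnaire row with all signs "no" unless overridden
make_response <- function(dog_id = "d1", ...) {
  resp <- list(dog_id = dog_id, sign_limp_end = "no", sign_limp_length = "no",
               sign_stiff_base = "no", sign_hair_on_end = "no",
               sign_painful = "no", attribution = "none")
  over <- list(...)
  resp[names(over)] <- over
  resp
}
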