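# Independent oracles and fixture builders shared across tests.
# These deliberately use naive loop-based computations so they stay
# independent of the package's vectorized implementations.

# Brute-force observed-data log-likelihood of the binary latent class
# mixture: sum_n log sum_c delta_c prod_i tau_ci^y (1 - tau_ci)^(1 - y).
brute_mixture_loglik <- function(Y, delta, tau) {
  ll <- 0
  for (n in seq_len(nrow(Y))) {
    p <- 0
    for (c in seq_along(delta)) {
      prod_i <- 1
      for (i in seq_len(ncol(Y))) {
        prod_i <- prod_i *
          (if (Y[n, i] == 1) tau[c, i] else 1 - tau[c, i])
      }
      p <- p + delta[c] * prod_i
    }
    ll <- ll + log(p)
  }
  ll
}

# Brute-force Pearson chi-square on a counts matrix.
brute_chisq <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Minimal schema-conformant couple rows for cohort tests. Every field takes
# an eligible default; override per row via ...
toy_couple <- function(n = 1, ...) {
  base <- tibble::tibble(
    couple_id = seq_len(n), cluster_id = 1L, stratum_id = 1L,
    hh_weight = 1, wife_weight = 1, husband_weight = 1,
    wife_method = "pill",
    husband_reports_nonbarrier_method = "none",
    husband_condom_last_sex = 0L,
    wife_age = 25L, husband_age = 30L,
    wife_education = "secondary", husband_education = "secondary",
    religion = "Hindu", caste = "OBC", residence = "rural",
    working = "no", wealth_quintile = 3L, living_children = 2L,
    region = "North", mobility_market = 1L, mobility_health = 1L,
    money_own = 0L, wife_wants_more = 1L, husband_wants_more = 1L,
    polygyny_flag = 0L, last_partner_not_wife_flag = 0L,
    used_after_last_coitus_flag = 0L, sterilized_flag = 0L,
    traditional_method_flag = 0L, nonuser_flag = 0L
  )
  for (item in attitude_items()) base[[item]] <- 1L
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Simulate an attitude matrix directly from a latent class model.
simulate_attitudes <- function(n, delta, tau, seed) {
  set.seed(seed)
  cls <- sample.int(length(delta), n, replace = TRUE, prob = delta)
  Y <- matrix(as.integer(runif(n * ncol(tau)) <
                           tau[cls, , drop = FALSE]), nrow = n)
  list(Y = Y, class = cls)
}
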