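# Independent oracles used across tests. These re-derive quantities by a
# different route than the package (per-trial products, exhaustive grids)
# so agreement is evidence, not tautology.

# log-likelihood as a literal per-trial Bernoulli product
oracle_bernoulli_loglik <- function(cells, p) {
  total <- 0
  for (i in seq_len(nrow(cells))) {
    trial_probs <- c(rep(p[i], cells$k[i]), rep(1 - p[i], cells$n[i] - cells$k[i]))
    total <- total + sum(log(trial_probs))
  }
  total
}

# best log-likelihood of the four-parameter model on an exhaustive coarse
# grid (values per axis chosen by the caller)
oracle_grid_loglik_4p <- function(cells, c_low_grid, width_grid,
                                  sigma_low_grid, sigma_high_grid,
                                  eps = 1e-6) {
  best <- -Inf
  for (cl in c_low_grid) for (w in width_grid)
    for (sl in sigma_low_grid) for (sh in sigma_high_grid) {
      p <- pnorm((cl + w - cells$soa) / sh) - pnorm((cl - cells$soa) / sl)
      p <- pmin(pmax(p, eps), 1 - eps)
      ll <- sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
      if (ll > best) best <- ll
    }
  best
}

oracle_grid_loglik_2p <- function(cells, c_grid, sigma_grid, eps = 1e-6) {
  best <- -Inf
  for (cc in c_grid) for (s in sigma_grid) {
    p <- pmin(pmax(pnorm((cells$soa - cc) / s), eps), 1 - eps)
    ll <- sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
    if (ll > best) best <- ll
  }
  best
}

# simulate one design-1-scale dataset (n trials per SOA) from given params
sim_cells <- function(params, soa, n) {
  k <- rbinom(length(soa), n, prob_simultaneous(params, soa))
  binomial_cells(soa, n, k)
}
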