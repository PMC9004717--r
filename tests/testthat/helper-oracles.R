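# Shared oracles and fixture builders.

# Monte-Carlo plug-in estimate of the generalized mutual information
# I_alpha = HC(T) + HC(S) + (1 - alpha) HC(T) HC(S) - HC(T,S),
# built only from the entropy kernel phi_alpha applied to known densities
# evaluated at simulated draws. Standard errors by batch means.
mc_mi_plugin <- function(sampler, dT, dS, dTS, alpha, n = 1e6, batches = 20) {
  draws <- sampler(n)
  phiT <- phi_alpha(pmax(dT(draws$t), 1e-300), alpha)
  phiS <- phi_alpha(pmax(dS(draws$s), 1e-300), alpha)
  phiTS <- phi_alpha(pmax(dTS(draws$t, draws$s), 1e-300), alpha)
  grp <- rep(seq_len(batches), length.out = n)
  per_batch <- vapply(seq_len(batches), function(b) {
    i <- grp == b
    hT <- mean(phiT[i]); hS <- mean(phiS[i]); hTS <- mean(phiTS[i])
    hT + hS + (1 - alpha) * hT * hS - hTS
  }, numeric(1))
  list(mi = mean(per_batch), se = stats::sd(per_batch) / sqrt(batches))
}

# samplers for the three closed-form families -------------------------------

mc_gaussian <- function(spec, alpha, n = 1e6) {
  sT <- spec$sigma_T; sS <- spec$sigma_S; r <- spec$rho
  sampler <- function(n) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    list(t = sT * z1, s = sS * (r * z1 + sqrt(1 - r^2) * z2))
  }
  dTS <- function(t, s) {
    q <- (t / sT)^2 - 2 * r * (t / sT) * (s / sS) + (s / sS)^2
    exp(-q / (2 * (1 - r^2))) / (2 * pi * sT * sS * sqrt(1 - r^2))
  }
  mc_mi_plugin(sampler,
               function(t) stats::dnorm(t, 0, sT),
               function(s) stats::dnorm(s, 0, sS),
               dTS, alpha, n)
}

mc_binary <- function(tab, alpha, n = 1e6) {
  cells <- as.vector(tab$cells)  # p00 p10 p01 p11
  sampler <- function(n) {
    k <- sample.int(4, n, replace = TRUE, prob = cells)
    list(t = c(0, 1, 0, 1)[k], s = c(0, 0, 1, 1)[k])
  }
  mc_mi_plugin(sampler,
               function(t) tab$pT[t + 1],
               function(s) tab$pS[s + 1],
               function(t, s) cells[1 + t + 2 * s], alpha, n)
}

mc_probit <- function(spec, alpha, n = 1e6) {
  r <- spec$rho
  sampler <- function(n) {
    zs <- stats::rnorm(n)
    u <- spec$mu_T + r * zs + sqrt(1 - r^2) * stats::rnorm(n)
    list(t = as.numeric(u >= 0), s = spec$mu_S + spec$sigma_S * zs)
  }
  p1s <- function(s) {
    stats::pnorm((spec$mu_T + r * (s - spec$mu_S) / spec$sigma_S) / sqrt(1 - r^2))
  }
  mc_mi_plugin(sampler,
               function(t) ifelse(t == 1, spec$p1, spec$p0),
               function(s) stats::dnorm(s, spec$mu_S, spec$sigma_S),
               function(t, s) {
                 p <- p1s(s)
                 ifelse(t == 1, p, 1 - p) * stats::dnorm(s, spec$mu_S, spec$sigma_S)
               }, alpha, n)
}

# random non-degenerate 2x2 tables via Dirichlet-like normalization
random_tables <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      p <- stats::rgamma(4, 1)
      p <- p / sum(p)
      if (all(p > 1e-4)) return(binary_table(p[1], p[2], p[3], p[4]))
    }
  })
}

# small Markov-by-construction config used across longitudinal tests
markov_test_config <- function(n_per_arm = 100, seed = 20220131L) {
  trial_config(n_control = n_per_arm, n_treatment = n_per_arm, seed = seed)
}
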