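test_that("design subsets validate and bad designs fail informatively", {
  expect_error(design_subset(c(24, 48)), "baseline")
  expect_error(design_subset(c(0, 48, 24)), "is not TRUE")
  d <- generate_trial(trial_config(n_control = 60, n_treatment = 60))
  expect_error(arm_conditional_mi(d, c(0, 12), 1), "absent from the data")
  # constant endpoint within an arm
  d2 <- d
  d2$subjects$endpoint[d2$subjects$arm == 1] <- 1
  expect_error(arm_conditional_mi(d2, c(0, 24), 1), "constant within arm")
})

test_that("arm-weighted information lies between the per-arm values", {
  d <- generate_trial(trial_config(n_control = 120, n_treatment = 80))
  for (a in c(0.5, 1, 2)) {
    mi <- arm_conditional_mi(d, c(0, 24, 48), a)
    det <- attr(mi, "detail")
    expect_gte(as.numeric(mi), min(det$per_arm) - 1e-12)
    expect_lte(as.numeric(mi), max(det$per_arm) + 1e-12)
    # and equals the explicit weighted average
    expect_equal(as.numeric(mi), sum(det$per_arm * det$weights))
    expect_equal(sum(det$weights), 1)
  }
})

test_that("single-index reduction recovers a known latent-probit model", {
  set.seed(55)
  n <- 6000
  S <- cbind(wk0 = stats::rnorm(n), wk24 = stats::rnorm(n))
  V_true <- 0.9 * S[, 1] + 0.6 * S[, 2]
  y <- as.numeric(-0.2 + V_true + stats::rnorm(n) > 0)
  spec <- single_index_reduction(y, S)
  sdV <- stats::sd(V_true)
  expect_equal(spec$rho, sdV / sqrt(1 + sdV^2), tolerance = 0.05)
  expect_equal(spec$p1, mean(y))
  expect_equal(spec$sigma_S, sdV, tolerance = 0.1)
})

test_that("plug-in arm information converges to the generative truth", {
  # truth from the generator's latent model: within an arm the index is
  # standardized, U = a0 + a1 z + a2 X + e, so p1 = Phi((a0+a1 z)/sqrt(1+a2^2)),
  # rho = a2/sqrt(1+a2^2), sigma of the fitted index ~ a2
  errs <- c()
  for (n in c(500, 2000, 8000)) {
    cfg <- trial_config(n_control = n / 2, n_treatment = n / 2, seed = 71L)
    d <- generate_trial(cfg)
    mi <- arm_conditional_mi(d, c(0, 24, 48, 72, 96), 1)
    scale <- sqrt(1 + cfg$a2^2)
    rho_true <- cfg$a2 / scale
    truth <- 0
    for (z in 0:1) {
      p1z <- stats::pnorm((cfg$a0 + cfg$a1 * z) / scale)
      truth <- truth +
        0.5 * probit_mutual_info(probit_pair(p1z, 1, rho_true), 1)$mi
    }
    errs <- c(errs, abs(as.numeric(mi) - truth))
  }
  expect_lt(errs[3], errs[1])          # error shrinks with n
  expect_lt(errs[3] / truth, 0.2)      # and is within 20% at n = 8000
})

test_that("strong-correlation plug-in lands within 20% of the known value", {
  cfg <- trial_config(n_control = 1000, n_treatment = 1000,
                      a2 = 2.06, seed = 72L)   # rho_latent ~ 0.9
  d <- generate_trial(cfg)
  mi <- arm_conditional_mi(d, c(0, 24, 48, 72, 96), 1)
  scale <- sqrt(1 + cfg$a2^2)
  truth <- 0
  for (z in 0:1) {
    p1z <- stats::pnorm((cfg$a0 + cfg$a1 * z) / scale)
    truth <- truth +
      0.5 * probit_mutual_info(probit_pair(p1z, 1, cfg$a2 / scale), 1)$mi
  }
  expect_lt(abs(as.numeric(mi) - truth) / truth, 0.2)
})

test_that("uninformative surrogate stays below its permutation null", {
  cfg <- trial_config(n_control = 100, n_treatment = 100, a2 = 0, seed = 73L)
  d <- generate_trial(cfg)
  obs <- as.numeric(arm_conditional_mi(d, c(0, 24), 1))
  # permutation null for the arm measure: endpoint shuffled within arm
  set.seed(74)
  nulls <- replicate(40, {
    dp <- d
    for (z in 0:1) {
      idx <- which(dp$subjects$arm == z)
      dp$subjects$endpoint[idx] <- dp$subjects$endpoint[sample(idx)]
    }
    as.numeric(arm_conditional_mi(dp, c(0, 24), 1))
  })
  expect_lt(obs, stats::quantile(nulls, 0.95))
})

test_that("adding a pure-noise visit barely moves the arm information", {
  cfg <- trial_config(n_control = 150, n_treatment = 150, seed = 75L)
  d <- generate_trial(cfg)
  # replace week 96 by pure noise, unrelated to everything
  set.seed(76)
  idx <- d$visits$week == 96
  d_noise <- d
  d_noise$visits$surrogate[idx] <- stats::rnorm(sum(idx), 0.8, 0.03)
  base <- as.numeric(arm_conditional_mi(d, c(0, 24, 48), 1))
  with_noise <- as.numeric(arm_conditional_mi(d_noise, c(0, 24, 48, 96), 1))
  # permutation spread of the base design calibrates "barely"
  set.seed(77)
  nulls <- replicate(30, {
    dp <- d
    for (z in 0:1) {
      i <- which(dp$subjects$arm == z)
      dp$subjects$endpoint[i] <- dp$subjects$endpoint[sample(i)]
    }
    as.numeric(arm_conditional_mi(dp, c(0, 24, 48), 1))
  })
  expect_lt(abs(with_noise - base), max(stats::quantile(nulls, 0.95), 0.05))
})

test_that("Prentice measure: near zero for Markov data, clearly positive with a direct effect", {
  d_markov <- generate_markov_trial(markov_test_config(seed = 81L))
  d_direct <- generate_trial(markov_test_config(seed = 82L))
  for (a in c(1, 2)) {
    mk <- as.numeric(prentice_conditional_mi(d_markov, c(0, 24, 48), a))
    dr <- as.numeric(prentice_conditional_mi(d_direct, c(0, 24, 48), a))
    expect_gt(dr, 5 * mk)
  }
})

test_that("information decreases in alpha on a fitted model (0.5 > 1 > 2)", {
  d <- generate_trial(markov_test_config(seed = 83L))
  tz <- vapply(c(0.5, 1, 2), function(a) {
    as.numeric(prentice_conditional_mi(d, c(0, 24, 48), a))
  }, numeric(1))
  expect_true(all(diff(tz) < 0))
  ts <- vapply(c(0.5, 1, 2), function(a) {
    as.numeric(arm_conditional_mi(d, c(0, 24, 48), a))
  }, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("design sweep is consistent, reproducible, and records failures", {
  d <- generate_trial(trial_config(n_control = 80, n_treatment = 80, seed = 84L))
  rep1 <- design_sweep(d, list(c(0, 24), c(0, 24, 48)), c(0.5, 1, 2))
  expect_equal(nrow(rep1), 6)
  expect_true(all(is.na(rep1$error)))
  expect_true(all(rep1$itma_TS > 0 & rep1$itma_TS < 1))
  # row matches the individual operations
  i <- which(rep1$design == "0, 24" & rep1$alpha == 2)
  expect_equal(rep1$mi_TS_given_Z[i],
               as.numeric(arm_conditional_mi(d, c(0, 24), 2)))
  expect_equal(rep1$mi_TZ_given_S[i],
               as.numeric(prentice_conditional_mi(d, c(0, 24), 2)))
  # ITMA columns are monotone transforms of the MI columns
  expect_equal(order(rep1$mi_TS_given_Z), order(rep1$itma_TS))
  expect_equal(rep1$itma_TS, itma_from_mi(rep1$mi_TS_given_Z))
  # reproducibility
  rep2 <- design_sweep(d, list(c(0, 24), c(0, 24, 48)), c(0.5, 1, 2))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  # a failing design is recorded, not fatal
  rep3 <- design_sweep(d, list(c(0, 24), c(0, 12)), 1)
  expect_true(any(!is.na(rep3$error)))
  expect_true(any(is.na(rep3$error)))
})
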