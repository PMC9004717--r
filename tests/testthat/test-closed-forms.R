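test_that("Gaussian mutual information: Shannon values, independence, boundaries", {
  expect_equal(gaussian_mutual_info(gaussian_pair(1, 1, 0.8), 1)$mi,
               -0.5 * log(0.36))
  expect_equal(gaussian_mutual_info(gaussian_pair(2, 0.3, 0), 2)$mi, 0)
  expect_equal(gaussian_mutual_info(gaussian_pair(2, 0.3, 0), 2)$itma, 0)
  # |rho| = 1: infinite for alpha >= 1, finite supremum for alpha < 1
  expect_true(is.infinite(gaussian_mutual_info(gaussian_pair(1, 1, 1), 1)$mi))
  expect_true(is.infinite(gaussian_mutual_info(gaussian_pair(1, 1, 1), 2)$mi))
  s <- 1 / sqrt(2 * pi)
  expect_equal(gaussian_mutual_info(gaussian_pair(s, s, 1), 0.5)$mi,
               1 / (0.5 * 0.5))
})

test_that("Gaussian MI is scale dependent only away from the Shannon order", {
  a1 <- gaussian_mutual_info(gaussian_pair(1, 1, 0.6), 1)$mi
  a2 <- gaussian_mutual_info(gaussian_pair(3, 0.2, 0.6), 1)$mi
  expect_equal(a1, a2)
  b1 <- gaussian_mutual_info(gaussian_pair(1, 1, 0.6), 2)$mi
  b2 <- gaussian_mutual_info(gaussian_pair(3, 0.2, 0.6), 2)$mi
  expect_gt(abs(b1 - b2), 1e-6)
})

test_that("Gaussian MI increases strictly in |rho| for all orders", {
  rhos <- seq(0, 0.99, by = 0.03)
  for (a in c(0.5, 1, 2)) {
    mis <- vapply(rhos, function(r) {
      gaussian_mutual_info(gaussian_pair(0.7, 1.3, r), a)$mi
    }, numeric(1))
    expect_true(all(diff(mis) > 0))
    neg <- vapply(-rhos, function(r) {
      gaussian_mutual_info(gaussian_pair(0.7, 1.3, r), a)$mi
    }, numeric(1))
    expect_equal(mis, neg)
  }
})

test_that("alpha < 1 Gaussian ITMA normalization lands in [0, 1] and hits 1 at the supremum", {
  for (sig in c(0.2, 1, 3)) {
    res <- gaussian_mutual_info(gaussian_pair(sig, sig, 0.7), 0.5)
    expect_equal(res$normalization_kind, "alpha_lt1_sup")
    expect_gte(res$itma_normalized, res$itma)
    expect_lte(res$itma_normalized, 1)
    at_sup <- gaussian_mutual_info(gaussian_pair(sig, sig, 1), 0.5)
    expect_equal(at_sup$itma_normalized, 1, tolerance = 1e-12)
  }
})

test_that("entropy-power ratio differs from the ITMA away from Shannon order", {
  # (EP(T) - EP(T|S)) / EP(T) is NOT 1 - exp(-2 I_alpha) for alpha != 1
  sT <- 1; sS <- 1; rho <- 0.6; a <- 2
  ep_T <- entropy_power(hc_entropy_gaussian(sT, a), 1)
  ep_TgS <- entropy_power(hc_entropy_gaussian(sT * sqrt(1 - rho^2), a), 1)
  ratio <- (ep_T - ep_TgS) / ep_T
  itma <- gaussian_mutual_info(gaussian_pair(sT, sS, rho), a)$itma
  expect_gt(abs(ratio - itma), 1e-3)
})

test_that("binary table construction, margins-and-rho round trip, range errors", {
  tab <- binary_table_from_margins_rho(0.5, 0.5, 0)
  expect_equal(as.vector(tab$cells), rep(0.25, 4))
  tab1 <- binary_table_from_margins_rho(0.5, 0.5, 1)
  expect_equal(as.vector(tab1$cells), c(0.5, 0, 0, 0.5))
  set.seed(5)
  for (i in 1:50) {
    m <- stats::runif(2, 0.05, 0.95)
    b <- binary_rho_bounds(m[1], m[2])
    r <- stats::runif(1, b[1], b[2])
    tab <- binary_table_from_margins_rho(m[1], m[2], r)
    expect_equal(tab$pT[2], m[1], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(tab$pS[2], m[2], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(tab$rho, r, tolerance = 1e-9)
  }
  expect_error(binary_table_from_margins_rho(0.7, 0.3, 0.9), "admissible interval")
  expect_error(binary_table(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("binary mutual information: independence, perfect dependence, Shannon branch", {
  set.seed(6)
  for (i in 1:20) {
    m <- stats::runif(2, 0.1, 0.9)
    prod_tab <- binary_table_from_margins_rho(m[1], m[2], 0)
    for (a in c(0.5, 1, 2)) {
      expect_equal(binary_mutual_info(prod_tab, a)$mi, 0, tolerance = 1e-14)
    }
  }
  perfect <- binary_table(0.5, 0, 0, 0.5)
  expect_equal(binary_mutual_info(perfect, 2)$mi, 0.25)
  expect_equal(binary_mutual_info(perfect, 1)$mi, log(2))
  # Eq.-(6)-style decomposition cross-check at alpha = 2
  hT <- hc_entropy_discrete(perfect$pT, 2)
  hS <- hc_entropy_discrete(perfect$pS, 2)
  hTS <- hc_entropy_discrete(as.vector(perfect$cells), 2)
  expect_equal(binary_mutual_info(perfect, 2)$mi,
               hT + hS + (1 - 2) * hT * hS - hTS)
})

test_that("binary MI is symmetric and bounded by the margin-constrained maximum", {
  tabs <- random_tables(60, seed = 21)
  for (tab in tabs) {
    swapped <- binary_table(tab$cells[1, 1], tab$cells[1, 2],
                            tab$cells[2, 1], tab$cells[2, 2])
    for (a in c(0.5, 1, 2)) {
      expect_equal(binary_mutual_info(tab, a)$mi,
                   binary_mutual_info(swapped, a)$mi, tolerance = 1e-12)
      expect_lte(binary_mutual_info(tab, a)$mi,
                 binary_mi_max(tab$pT[2], tab$pS[2], a) + 1e-10)
    }
  }
  expect_equal(binary_mi_max(0.5, 0.5, 2), 0.25)
  expect_equal(binary_mi_max(0.5, 0.5, 1), log(2))
})

test_that("order-2 MI is capped by the marginal entropies and the margin maximum", {
  tabs <- random_tables(1000, seed = 33)
  for (tab in tabs) {
    hT2 <- hc_entropy_discrete(tab$pT, 2)
    hS2 <- hc_entropy_discrete(tab$pS, 2)
    expect_lte(binary_mutual_info(tab, 2)$mi, min(hT2, hS2) + 1e-12)
    expect_lte(binary_mutual_info(tab, 0.5)$mi,
               binary_mi_max(tab$pT[2], tab$pS[2], 0.5) + 1e-10)
  }
})

test_that("discordant tables give (slightly) negative non-additive MI away from order 1", {
  tab <- binary_table(0.1, 0.2, 0.3, 0.4)   # implied correlation < 0
  res <- binary_mutual_info(tab, 2)
  expect_lt(res$mi, 0)
  expect_equal(res$mi, sum(tab$cells^2) - sum(outer(tab$pT, tab$pS)^2))
  expect_lt(res$itma, 0)                    # monotone transform keeps the sign
  expect_equal(binary_mutual_info(tab, 1)$mi > 0, TRUE)  # Shannon MI is >= 0
})

test_that("binary MI is monotone in rho under the proof's concordance condition", {
  # the derivative of I_alpha in rho is positive iff
  # sign(1-alpha) * (p10^(a-1) + p01^(a-1) - p00^(a-1) - p11^(a-1)) > 0
  set.seed(44)
  for (i in 1:200) {
    m <- stats::runif(2, 0.15, 0.85)
    b <- binary_rho_bounds(m[1], m[2])
    r <- sort(stats::runif(2, b[1] + 0.02, b[2] - 0.02))
    for (a in c(0.5, 2)) {
      t1 <- binary_table_from_margins_rho(m[1], m[2], r[1])
      t2 <- binary_table_from_margins_rho(m[1], m[2], r[2])
      cond <- function(tab) {
        c_ <- tab$cells
        (c_[1, 1]^(a - 1) + c_[2, 2]^(a - 1)) -
          (c_[2, 1]^(a - 1) + c_[1, 2]^(a - 1))
      }
      # increasing over [r1, r2] only guaranteed when the condition holds
      # with the same sign throughout; check the derivative sign locally
      eps <- 1e-5
      if (r[1] + eps < b[2]) {
        d1 <- binary_mutual_info(
          binary_table_from_margins_rho(m[1], m[2], r[1] + eps), a)$mi -
          binary_mutual_info(t1, a)$mi
        cnd <- cond(t1)
        if (a > 1 && cnd > 1e-8) expect_gt(d1, 0)
        if (a < 1 && cnd < -1e-8) expect_gt(d1, 0)
      }
    }
  }
})

test_that("probit MI vanishes at rho = 0 and matches the Owen form at order 2", {
  for (p1 in c(0.2, 0.5, 0.8)) {
    for (a in c(0.5, 1, 2)) {
      expect_equal(probit_mutual_info(probit_pair(p1, 1.7, 0), a)$mi, 0,
                   tolerance = 1e-12)
    }
  }
  for (p1 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (rho in c(-0.9, -0.4, 0.2, 0.6, 0.95)) {
      s <- probit_pair(p1, 0.8, rho)
      expect_equal(probit_mutual_info(s, 2)$mi, probit_mi_alpha2_owen(s),
                   tolerance = 1e-8)
    }
  }
})

test_that("probit MI approaches its printed perfect-correlation limit", {
  expect_equal(probit_mi_rho_limit(probit_pair(0.5, sqrt(1 / (2 * pi))), 2),
               1 / (2 * sqrt(2)))
  # at rho = 1 - 1e-6 the value is within 1e-3 of the limit (the boundary
  # gap closes like sqrt(1 - rho^2))
  s0 <- probit_pair(0.5, sqrt(1 / (2 * pi)), 1 - 1e-6)
  expect_lt(abs(probit_mutual_info(s0, 2)$mi -
                  probit_mi_rho_limit(s0, 2)), 1e-3)
  for (p1 in c(0.3, 0.6)) for (a in c(0.5, 2)) {
    lim <- probit_mi_rho_limit(probit_pair(p1, 1.2), a)
    near_pos <- probit_mutual_info(probit_pair(p1, 1.2, 1 - 1e-6), a)$mi
    near_neg <- probit_mutual_info(probit_pair(p1, 1.2, -(1 - 1e-6)), a)$mi
    expect_lt(abs(near_pos - lim) / lim, 0.01)
    expect_lt(abs(near_neg - lim) / lim, 0.01)
    # approach is monotone in rho near the boundary
    nearer <- probit_mutual_info(probit_pair(p1, 1.2, 1 - 1e-8), a)$mi
    expect_lt(abs(nearer - lim), abs(near_pos - lim))
  }
  expect_error(probit_mi_rho_limit(probit_pair(0.5, 1), 1), "diverges")
  expect_error(probit_mutual_info(probit_pair(0.5, 1, 1), 2), "rho_limit")
})

test_that("all three families are continuous in alpha at the Shannon point", {
  g <- gaussian_pair(0.7, 1.4, 0.55)
  tab <- binary_table(0.3, 0.25, 0.15, 0.3)
  pp <- probit_pair(0.4, 1, 0.5)
  for (fam in list(
    function(a) gaussian_mutual_info(g, a)$mi,
    function(a) binary_mutual_info(tab, a)$mi,
    function(a) probit_mutual_info(pp, a)$mi)) {
    at1 <- fam(1)
    expect_lt(abs(fam(1 + 1e-4) - at1), 1e-4)
    expect_lt(abs(fam(1 - 1e-4) - at1), 1e-4)
  }
})

test_that("ITMA transform and its discrete normalization", {
  expect_equal(itma_from_mi(0), 0)
  expect_equal(itma_from_mi(0.5), 1 - exp(-1))
  expect_equal(itma_from_mi(Inf), 1)
  expect_error(itma_from_mi(-1e-6), "negative")
  expect_equal(itma_from_mi(-1e-14), 0)  # roundoff clamp
  expect_equal(itma_normalize_discrete_shannon(0, 0.4), 0)
  hT <- log(2)
  expect_equal(itma_normalize_discrete_shannon(1 - exp(-2 * hT), hT), 1)
  expect_error(itma_normalize_discrete_shannon(0.2, 0), "degenerate")
  # fair-coin endpoint with perfect dependence saturates the normalized ITMA
  res <- binary_mutual_info(binary_table(0.5, 0, 0, 0.5), 1)
  expect_equal(itma_normalize_discrete_shannon(res$itma, log(2)), 1)
})

test_that("probit Shannon ITMA carries the discrete-endpoint normalization", {
  res <- probit_mutual_info(probit_pair(0.3, 1, 0.7), 1)
  expect_equal(res$normalization_kind, "discrete_shannon_max")
  expect_gte(res$itma_normalized, res$itma)
  expect_lte(res$itma_normalized, 1)
  # Shannon MI of a binary endpoint is capped by its entropy
  expect_lte(res$mi, hc_entropy_discrete(c(0.3, 0.7), 1))
})
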