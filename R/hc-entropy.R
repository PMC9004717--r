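#' Havrda-Charvat information function
#'
#' The kernel \eqn{\varphi_\alpha} that generates the Havrda-Charvat entropy
#' \eqn{HC_\alpha(X) = E[\varphi_\alpha(f(X))]}:
#' \deqn{\varphi_\alpha(x) = (x^{\alpha-1} - 1)/(1 - \alpha), \quad \alpha \neq 1,}
#' \deqn{\varphi_1(x) = -\log x.}
#' The two branches join continuously as \eqn{\alpha \to 1}.
#'
#' @param x positive numeric vector (density or probability values).
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Numeric vector, \eqn{\varphi_\alpha(x)}.
#' @examples
#' phi_alpha(0.5, 2)       # 0.5
#' phi_alpha(0.5, 1)       # log(2)
#' @export
phi_alpha <- function(x, order) {
  order <- alpha_order(order)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("phi_alpha() requires strictly positive finite 'x'", call. = FALSE)
  }
  if (order$shannon) -log(x) else (x^(order$alpha - 1) - 1) / (1 - order$alpha)
}

#' Discrete Havrda-Charvat entropy
#'
#' \eqn{HC_\alpha(p) = (\sum_i p_i^\alpha - 1)/(1-\alpha)} for
#' \eqn{\alpha \neq 1}; Shannon entropy \eqn{-\sum_i p_i \log p_i} at
#' \eqn{\alpha = 1}. Zero-probability cells contribute nothing for every
#' \eqn{\alpha > 0} (the \eqn{0 \log 0 = 0} convention), so degenerate
#' distributions have entropy 0.
#'
#' @param p numeric vector of probabilities summing to one.
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Non-negative scalar entropy (natural-log units at \eqn{\alpha=1}).
#' @examples
#' hc_entropy_discrete(c(0.5, 0.5), 2)  # 0.5
#' hc_entropy_discrete(c(0.5, 0.5), 1)  # log(2)
#' @export
hc_entropy_discrete <- function(p, order) {
  order <- alpha_order(order)
  p <- validate_probs(p)
  p <- p[p > 0]
  if (order$shannon) -sum(p * log(p)) else (sum(p^order$alpha) - 1) / (1 - order$alpha)
}

validate_probs <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p))) {
    stop("probabilities must be finite numbers", call. = FALSE)
  }
  if (any(p < -tol)) stop("probabilities must be non-negative", call. = FALSE)
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must sum to 1 (within 1e-12); got ",
         format(sum(p), digits = 15), call. = FALSE)
  }
  p
}

#' Density specification for continuous entropy
#'
#' Wraps a (vectorised) density evaluator together with its support and an
#' optional uniform bound, for use by [hc_entropy_continuous()]. The bound
#' plays the role of the constant that guarantees existence of
#' \eqn{HC_\alpha} for \eqn{\alpha > 1} (any bounded density has finite
#' Havrda-Charvat entropy of order greater than one, heavy tails included).
#'
#' @param evaluator function mapping a numeric vector to non-negative
#'   density values.
#' @param support length-2 numeric, possibly infinite, the support interval.
#' @param bound optional positive scalar, a uniform bound on the density.
#' @return An object of class `"density_spec"`.
#' @examples
#' dspec <- density_spec(dnorm, c(-Inf, Inf), bound = dnorm(0))
#' hc_entropy_continuous(dspec, 1)  # 0.5 * (1 + log(2 * pi))
#' @export
density_spec <- function(evaluator, support = c(-Inf, Inf), bound = NULL) {
  stopifnot(is.function(evaluator), length(support) == 2L,
            support[1] < support[2])
  if (!is.null(bound)) stopifnot(is.numeric(bound), bound > 0)
  structure(list(evaluator = evaluator, support = as.numeric(support),
                 bound = bound),
            class = "density_spec")
}

#' Continuous Havrda-Charvat entropy by adaptive quadrature
#'
#' Computes \eqn{HC_\alpha(X) = \int \varphi_\alpha(f(x)) f(x)\,dx} for a
#' density given as a [density_spec]. At \eqn{\alpha = 1} this is the
#' differential Shannon entropy, which need not exist: for heavy-tailed
#' densities such as [heavy_tail_density()] the integral grows without bound.
#' Divergence is detected at run time by integrating over truncations
#' \eqn{[-M, M]} with doubling \eqn{M}: when the accumulated integral is
#' still changing by more than a relative `1e-3` per doubling at
#' \eqn{M = 2^{20}}, the value is declared divergent and `Inf` is returned
#' (with attribute `divergent = TRUE`). Quadrature failure, by contrast,
#' raises an error.
#'
#' @param f a [density_spec].
#' @param order entropy order, an [alpha_order] or a positive number.
#' @param rel.tol relative tolerance passed to [stats::integrate()].
#' @return Scalar entropy; `Inf` with attribute `divergent` when the
#'   integral fails to plateau.
#' @examples
#' hc_entropy_continuous(density_spec(dnorm), 2)  # 1 - 1/sqrt(2)... at sigma 1
#' @export
hc_entropy_continuous <- function(f, order, rel.tol = 1e-10) {
  stopifnot(inherits(f, "density_spec"))
  order <- alpha_order(order)
  integrand <- function(x) {
    fx <- f$evaluator(x)
    out <- numeric(length(fx))
    pos <- fx > 0
    out[pos] <- phi_alpha(fx[pos], order) * fx[pos]
    out
  }
  lo <- f$support[1]; hi <- f$support[2]
  if (is.finite(lo) && is.finite(hi)) {
    val <- integrate_or_fail(integrand, lo, hi, rel.tol)
    return(val)
  }
  # Infinite support: accumulate over doubling truncations so that slow
  # (log log M) divergence of the Shannon integral is caught rather than
  # silently truncated away.
  M0 <- 1
  total <- integrate_or_fail(integrand, max(lo, -M0), min(hi, M0), rel.tol)
  M <- M0
  prev_total <- total
  repeat {
    M2 <- 2 * M
    inc <- 0
    if (hi > M)  inc <- inc + integrate_or_fail(integrand, M, min(hi, M2), rel.tol)
    if (lo < -M) inc <- inc + integrate_or_fail(integrand, max(lo, -M2), -M, rel.tol)
    total <- total + inc
    relchg <- abs(total - prev_total) / max(abs(total), 1e-12)
    if (M2 >= 2^20) {
      if (relchg > 1e-3) {
        return(structure(Inf, divergent = TRUE))
      }
      return(total)
    }
    if (relchg < rel.tol * 10 && M2 >= 64) return(total)
    prev_total <- total
    M <- M2
  }
}

integrate_or_fail <- function(fun, lo, hi, rel.tol) {
  res <- tryCatch(
    stats::integrate(fun, lo, hi, rel.tol = rel.tol, abs.tol = 1e-12,
                     subdivisions = 500L, stop.on.error = FALSE),
    error = function(e) stop("quadrature failed on [", lo, ", ", hi, "]: ",
                             conditionMessage(e), call. = FALSE))
  if (!res$message %in% c("OK", "roundoff error was detected")) {
    stop("quadrature did not converge on [", lo, ", ", hi, "]: ",
         res$message, call. = FALSE)
  }
  res$value
}

#' Havrda-Charvat entropy of a Gaussian, closed form
#'
#' \deqn{HC_\alpha(X) = \frac{1}{1-\alpha}\left[\frac{(2\pi\sigma^2)^{(1-\alpha)/2}}{\sqrt{\alpha}} - 1\right]}
#' for \eqn{\alpha \neq 1}, and the familiar
#' \eqn{\frac{1}{2}\log(2\pi e \sigma^2)} at \eqn{\alpha = 1}.
#'
#' @param sigma positive scalar, the standard deviation.
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Scalar entropy.
#' @examples
#' hc_entropy_gaussian(1, 1)                   # 0.5 * (1 + log(2*pi))
#' hc_entropy_gaussian(sqrt(1 / (2 * pi)), 2)  # 1 - 1/sqrt(2)
#' @export
hc_entropy_gaussian <- function(sigma, order) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  order <- alpha_order(order)
  if (order$shannon) return(0.5 * log(2 * pi * exp(1) * sigma^2))
  a <- order$alpha
  ((2 * pi * sigma^2)^((1 - a) / 2) / sqrt(a) - 1) / (1 - a)
}

#' Joint entropy of independent variables under non-additivity
#'
#' Havrda-Charvat entropy is non-additive: for independent \eqn{T} and
#' \eqn{S},
#' \deqn{HC_\alpha(T,S) = HC_\alpha(T) + HC_\alpha(S) + (1-\alpha) HC_\alpha(T) HC_\alpha(S),}
#' which reduces to ordinary additivity at \eqn{\alpha = 1}.
#'
#' @param hT,hS entropies of the two components at the same order.
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Scalar joint entropy under independence.
#' @export
nonadditive_joint_under_independence <- function(hT, hS, order) {
  order <- alpha_order(order)
  hT + hS + (1 - order$alpha) * hT * hS
}

#' Entropy power
#'
#' \eqn{EP_\alpha(X) = e^{2 HC_\alpha(X)/n} / (2\pi e)}: the variance of the
#' isotropic Gaussian in dimension `n` whose entropy equals `h`. All uses in
#' this package are univariate (`n = 1`); the dimension argument is kept for
#' completeness.
#'
#' @param h entropy value.
#' @param n positive integer dimension.
#' @param order entropy order (unused in the formula; accepted so call sites
#'   can document which family `h` came from).
#' @return Positive scalar.
#' @examples
#' entropy_power(hc_entropy_gaussian(1, 1), 1)  # 1: unit-variance Gaussian
#' @export
entropy_power <- function(h, n = 1L, order = 1) {
  stopifnot(is.numeric(h), length(h) == 1L, n >= 1, n == as.integer(n))
  exp(2 * h / n) / (2 * pi * exp(1))
}
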