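#' Latent-probit binary/continuous pair specification
#'
#' A binary clinical endpoint \eqn{T} generated by thresholding a latent
#' normal \eqn{U \sim N(\Phi^{-1}(p_1), 1)} at zero (\eqn{T = 1
#' \Leftrightarrow U \ge 0}), paired with a Gaussian surrogate
#' \eqn{S \sim N(\mu_S, \sigma_S^2)}; \eqn{\rho} is the correlation of the
#' latent \eqn{(U, S)} pair. The conditional success probability is
#' \deqn{P(T=1 \mid S=s) = \Phi\!\left(\frac{\Phi^{-1}(p_1) +
#'   \rho (s-\mu_S)/\sigma_S}{\sqrt{1-\rho^2}}\right).}
#' The latent mean is always recomputed as \eqn{\Phi^{-1}(p_1)}.
#'
#' @param p1 marginal success probability of the endpoint, in (0, 1).
#' @param sigma_S positive surrogate standard deviation.
#' @param rho latent correlation in \eqn{[-1, 1]}.
#' @param mu_S surrogate mean (does not affect mutual information).
#' @return An object of class `"probit_pair"`.
#' @export
probit_pair <- function(p1, sigma_S = 1, rho = 0, mu_S = 0) {
  stopifnot(p1 > 0, p1 < 1, sigma_S > 0, abs(rho) <= 1)
  structure(list(p1 = p1, p0 = 1 - p1, mu_T = stats::qnorm(p1),
                 mu_S = mu_S, sigma_S = sigma_S, rho = rho),
            class = "probit_pair")
}

#' Generalized mutual information of a latent-probit pair
#'
#' Closed form for the Havrda-Charvat mutual information between the
#' binary endpoint and the Gaussian surrogate of a [probit_pair()]:
#' \deqn{I_\alpha(T,S) = \frac{(2\pi\sigma_S^2)^{(1-\alpha)/2}}{(1-\alpha)\sqrt{\alpha}}
#'   \sum_{t=0}^{1}\left[p_t^\alpha -
#'   \Im_\alpha\!\left(\frac{\Phi^{-1}(p_t)}{\sqrt{1-\rho^2}},
#'   \frac{(-1)^{1-t}\rho}{\sqrt{\alpha(1-\rho^2)}}\right)\right],
#'   \qquad \alpha \neq 1,}
#' with \eqn{\Im_\alpha} the Gaussian-weighted CDF power integral
#' ([imath_integral()]). At \eqn{\alpha = 1} the Shannon limit
#' \deqn{I_1(T,S) = \sum_t\left[\int p_{t|y}\log p_{t|y}\,\phi(y)\,dy -
#'   p_t \log p_t\right]}
#' is used, with \eqn{p_{t|y} = \Phi((\Phi^{-1}(p_t) +
#' (-1)^{1-t}\rho y)/\sqrt{1-\rho^2})}; it does not depend on
#' \eqn{\sigma_S} and is bounded by the binary entropy of \eqn{T}.
#'
#' @param spec a [probit_pair()] with \eqn{|\rho| < 1}; the perfect-
#'   correlation boundary is handled by [probit_mi_rho_limit()].
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return An object of class `"hc_mi"`. At \eqn{\alpha = 1} the normalized
#'   ITMA divides by the cap \eqn{1 - e^{-2 h(T)}} for the discrete
#'   endpoint.
#' @examples
#' probit_mutual_info(probit_pair(0.5, 1, 0), 2)$mi  # 0: independence
#' @export
probit_mutual_info <- function(spec, order) {
  stopifnot(inherits(spec, "probit_pair"))
  order <- alpha_order(order)
  if (abs(spec$rho) >= 1) {
    stop("|rho| = 1: use probit_mi_rho_limit() for the perfect-correlation ",
         "boundary", call. = FALSE)
  }
  a <- order$alpha
  rho <- spec$rho
  p <- c(spec$p0, spec$p1)
  sgn <- c(-1, 1)                       # (-1)^(1-t) for t = 0, 1
  if (order$shannon) {
    mi <- 0
    for (t in 1:2) {
      ep <- stats::integrate(function(y) {
        pt_y <- stats::pnorm((stats::qnorm(p[t]) + sgn[t] * rho * y) /
                               sqrt(1 - rho^2))
        ifelse(pt_y > 0, pt_y * log(pt_y), 0) * stats::dnorm(y)
      }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
      subdivisions = 400L)$value
      mi <- mi + ep - p[t] * log(p[t])
    }
    hT <- hc_entropy_discrete(p, 1)
    r2 <- itma_from_mi(max(mi, 0))
    return(mutual_info_result(
      1, mi, itma_normalized = itma_normalize_discrete_shannon(r2, hT),
      normalization_kind = "discrete_shannon_max"))
  }
  pref <- (2 * pi * spec$sigma_S^2)^((1 - a) / 2) / ((1 - a) * sqrt(a))
  term <- 0
  for (t in 1:2) {
    term <- term + p[t]^a -
      imath_integral(stats::qnorm(p[t]) / sqrt(1 - rho^2),
                     sgn[t] * rho / sqrt(a * (1 - rho^2)), order)
  }
  mutual_info_result(a, pref * term)
}

#' Perfect-latent-correlation limit of the probit mutual information
#'
#' As \eqn{\rho \to \pm 1} the order-\eqn{\alpha} information of a
#' latent-probit pair converges (for \eqn{\alpha \neq 1}) to
#' \deqn{\frac{(2\pi\sigma_S^2)^{(1-\alpha)/2}}{(1-\alpha)\sqrt{\alpha}}
#'   \sum_{t=0}^{1}\left[p_t^\alpha - \Phi(\sqrt{\alpha}\,\Phi^{-1}(p_t))\right].}
#' The limit is the same for both signs of \eqn{\rho}. At \eqn{\alpha = 1}
#' the Shannon information diverges at perfect latent correlation and this
#' operation errors.
#'
#' @param spec a [probit_pair()]; its `rho` is ignored.
#' @param order entropy order with \eqn{\alpha \neq 1}.
#' @return Scalar limit value.
#' @examples
#' probit_mi_rho_limit(probit_pair(0.5, sqrt(1 / (2 * pi))), 2)  # 1/(2*sqrt(2))
#' @export
probit_mi_rho_limit <- function(spec, order) {
  stopifnot(inherits(spec, "probit_pair"))
  order <- alpha_order(order)
  if (order$shannon) {
    stop("Shannon mutual information diverges at |rho| = 1; the limit is ",
         "defined only for alpha != 1", call. = FALSE)
  }
  a <- order$alpha
  p <- c(spec$p0, spec$p1)
  pref <- (2 * pi * spec$sigma_S^2)^((1 - a) / 2) / ((1 - a) * sqrt(a))
  pref * sum(p^a - stats::pnorm(sqrt(a) * stats::qnorm(p)))
}

#' Owen's-T closed form at order 2
#'
#' For \eqn{\alpha = 2} the probit-pair information reduces, via the
#' identity \eqn{\Im_2(a,b) = \Phi(a/\sqrt{1+b^2}) -
#' 2T(a/\sqrt{1+b^2}, 1/\sqrt{1+2b^2})} and \eqn{T(h,k) = T(-h,k)}, to
#' \deqn{I_2(T,S) = \frac{1}{2\sqrt{\pi}\,\sigma_S}\left\{1 -
#'   4T\!\left(\frac{\Phi^{-1}(p_0)}{\sqrt{1-\rho^2/2}},
#'   \sqrt{1-\rho^2}\right) - p_1^2 - p_0^2\right\}.}
#' Agrees with `probit_mutual_info(spec, 2)` to near machine precision and
#' serves as its analytic cross-check.
#'
#' @param spec a [probit_pair()].
#' @return Scalar \eqn{I_2(T,S)}.
#' @export
probit_mi_alpha2_owen <- function(spec) {
  stopifnot(inherits(spec, "probit_pair"))
  rho <- spec$rho
  h <- stats::qnorm(spec$p0) / sqrt(1 - rho^2 / 2)
  (1 / (2 * sqrt(pi) * spec$sigma_S)) *
    (1 - 4 * owen_t(h, sqrt(1 - rho^2)) - spec$p1^2 - spec$p0^2)
}
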