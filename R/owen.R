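# Owen's T function and the bivariate normal CDF built on it.
# T(h,k) = phi(h) * int_0^k phi(h x)/(1+x^2) dx
#        = (1/2pi) * int_0^k exp(-h^2 (1+x^2)/2) / (1+x^2) dx.
# The integrand is smooth, so fixed-order Gauss-Legendre on the reduced
# range |k| <= 1 is accurate to near machine precision; |k| > 1 is folded
# back with Owen's reduction identity.

.quad_cache <- new.env(parent = emptyenv())

gl_nodes_01 <- function(n = 48L) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]])) {
    g <- pracma::gaussLegendre(n, 0, 1)
    .quad_cache[[key]] <- g
  }
  .quad_cache[[key]]
}

#' Owen's T function
#'
#' \deqn{T(h,k) = \phi(h)\int_0^k \frac{\phi(hx)}{1+x^2}\,dx,}
#' the classical ingredient of bivariate normal orthant probabilities.
#' Satisfies \eqn{T(h,k) = T(-h,k)} and \eqn{T(h,-k) = -T(h,k)}.
#' Evaluated by Gauss-Legendre quadrature after reducing \eqn{|k| \le 1}
#' via the identity
#' \eqn{T(h,k) = \frac{1}{2}[\Phi(h)+\Phi(hk)] - \Phi(h)\Phi(hk) - T(hk, 1/k)}
#' (for \eqn{h, k > 0}). Vectorised over `h` and `k`.
#'
#' @param h,k numeric vectors (recycled).
#' @return Numeric vector of Owen's T values.
#' @examples
#' owen_t(0, 1)       # arctan(1) / (2*pi) = 1/8
#' owen_t(0.5, Inf)   # pnorm(-0.5) / 2
#' @export
owen_t <- function(h, k) {
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  out <- numeric(n)
  ks <- sign(k)
  ha <- abs(h)
  ka <- abs(k)
  inf <- is.infinite(ka)
  out[inf] <- ks[inf] * 0.5 * stats::pnorm(-ha[inf])
  small <- !inf & ka <= 1
  if (any(small)) {
    out[small] <- ks[small] * owen_t_core(ha[small], ka[small])
  }
  big <- !inf & ka > 1
  if (any(big)) {
    hb <- ha[big]; kb <- ka[big]
    hk <- hb * kb
    red <- 0.5 * (stats::pnorm(hb) + stats::pnorm(hk)) -
      stats::pnorm(hb) * stats::pnorm(hk) - owen_t_core(hk, 1 / kb)
    out[big] <- ks[big] * red
  }
  out
}

# T(h,k) for h >= 0, 0 <= k <= 1, by 48-node Gauss-Legendre on x = k*u.
owen_t_core <- function(h, k) {
  g <- gl_nodes_01()
  x <- outer(g$x, k)                      # nodes x length(k)
  hx2 <- 1 + x^2
  integrand <- exp(-0.5 * rep(h^2, each = nrow(x)) * hx2) / hx2
  (k / (2 * pi)) * colSums(g$w * integrand)
}

#' Standard bivariate normal CDF
#'
#' \eqn{\Phi_2(h, k; \rho) = P(X \le h, Y \le k)} for standard normal
#' \eqn{(X, Y)} with correlation \eqn{\rho}, computed from Owen's T.
#' Vectorised over `h`, `k`, `rho`.
#'
#' @param h,k numeric vectors of upper limits (recycled).
#' @param rho correlation(s) in \eqn{[-1, 1]}.
#' @return Numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(abs(rho) > 1 + 1e-12)) stop("'rho' must lie in [-1, 1]", call. = FALSE)
  rho <- pmin(1, pmax(-1, rho))
  out <- numeric(n)

  hi <- abs(rho) >= 1 - 1e-14
  if (any(hi)) {
    pos <- hi & rho > 0
    out[pos] <- stats::pnorm(pmin(h[pos], k[pos]))
    neg <- hi & rho < 0
    out[neg] <- pmax(0, stats::pnorm(h[neg]) + stats::pnorm(k[neg]) - 1)
  }
  gen <- !hi
  if (!any(gen)) return(out)

  hg <- h[gen]; kg <- k[gen]; rg <- rho[gen]
  den <- sqrt(1 - rg^2)
  both0 <- hg == 0 & kg == 0
  res <- numeric(sum(gen))
  if (any(both0)) res[both0] <- 0.25 + asin(rg[both0]) / (2 * pi)
  rest <- !both0
  if (any(rest)) {
    hr <- hg[rest]; kr <- kg[rest]; rr <- rg[rest]; dr <- den[rest]
    ah <- ifelse(hr == 0, sign(kr) * Inf, (kr / hr - rr) / dr)
    ak <- ifelse(kr == 0, sign(hr) * Inf, (hr / kr - rr) / dr)
    beta <- ifelse(hr * kr < 0 | (hr * kr == 0 & (hr + kr) < 0), 0.5, 0)
    res[rest] <- 0.5 * (stats::pnorm(hr) + stats::pnorm(kr)) -
      owen_t(hr, ah) - owen_t(kr, ak) - beta
  }
  out[gen] <- pmin(1, pmax(0, res))
  out
}

#' Gaussian-weighted power of the normal CDF
#'
#' \deqn{\Im_\alpha(a, b) = \int_{-\infty}^{\infty} \Phi^\alpha(a + b y)\,\phi(y)\,dy,}
#' the building block of the latent-probit closed-form mutual information.
#' Computed by adaptive quadrature to absolute tolerance below `1e-10`:
#' fixed-node Gauss-Hermite rules degrade to ~`1e-4` here for orders below
#' one with \eqn{|b| > 2}, because \eqn{\Phi^\alpha(a+by)} carries its own
#' Gaussian-like factor on a different scale than the weight. For `b = 0`
#' the exact value \eqn{\Phi(a)^\alpha} is returned. At \eqn{\alpha = 2}
#' the result agrees with the Owen's-T identity
#' \eqn{\Phi(a/\sqrt{1+b^2}) - 2T(a/\sqrt{1+b^2}, 1/\sqrt{1+2b^2})}.
#'
#' @param a,b finite numeric vectors (recycled).
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Numeric vector of values in \eqn{(0, 1)}.
#' @examples
#' imath_integral(0, 0, 2)  # 0.25
#' @export
imath_integral <- function(a, b, order) {
  order <- alpha_order(order)
  alpha <- order$alpha
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("imath_integral() requires finite 'a' and 'b'", call. = FALSE)
  }
  out <- numeric(n)
  z0 <- b == 0
  out[z0] <- stats::pnorm(a[z0])^alpha
  idx <- which(!z0)
  for (i in idx) {
    res <- stats::integrate(
      function(y) stats::pnorm(a[i] + b[i] * y)^alpha * stats::dnorm(y),
      -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13, subdivisions = 400L,
      stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected")) {
      stop("quadrature for the CDF-power integral failed: ", res$message,
           call. = FALSE)
    }
    out[i] <- res$value
  }
  out
}
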