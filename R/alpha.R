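#' Entropy order
#'
#' Constructs the order parameter \eqn{\alpha > 0} of the Havrda-Charvat
#' entropy family. The family is non-additive for \eqn{\alpha \neq 1} and
#' reduces to Shannon entropy in the limit \eqn{\alpha \to 1}. Orders within
#' `1e-8` of 1 are routed to the exact Shannon branch, where the generic
#' formulas lose all significant digits to cancellation.
#'
#' @param alpha positive number, the entropy order.
#' @return An object of class `"alpha_order"`: a list with elements
#'   `alpha` (the order actually used) and `shannon` (logical, `TRUE` when
#'   the Shannon branch applies).
#' @examples
#' alpha_order(2)
#' alpha_order(1)$shannon
#' @export
alpha_order <- function(alpha) {
  if (inherits(alpha, "alpha_order")) return(alpha)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("'alpha' must be a single finite number", call. = FALSE)
  }
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  shannon <- abs(alpha - 1) < 1e-8
  if (shannon && alpha != 1) {
    message("alpha = ", format(alpha),
            " is within 1e-8 of 1; using the exact Shannon branch")
    alpha <- 1
  }
  structure(list(alpha = alpha, shannon = shannon), class = "alpha_order")
}

#' @export
print.alpha_order <- function(x, ...) {
  cat("Havrda-Charvat entropy order alpha =", format(x$alpha),
      if (x$shannon) "(Shannon branch)" else "", "\n")
  invisible(x)
}
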