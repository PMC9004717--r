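#' Joint distribution of two binary endpoints
#'
#' A 2x2 probability table for a binary clinical endpoint \eqn{T} and a
#' binary surrogate \eqn{S}, cell \eqn{p_{t,s} = P(T=t, S=s)}.
#'
#' @param p00,p10,p01,p11 cell probabilities (first index \eqn{T}, second
#'   \eqn{S}) summing to 1.
#' @return An object of class `"prob_table2x2"` with the cells, margins and
#'   the implied correlation
#'   \eqn{\rho = (p_{11} - p_{1+}p_{+1}) / \sqrt{p_{1+}p_{0+}p_{+1}p_{+0}}}.
#' @examples
#' binary_table(0.4, 0.1, 0.1, 0.4)$rho
#' @export
binary_table <- function(p00, p10, p01, p11) {
  p <- validate_probs(c(p00, p10, p01, p11))
  cells <- matrix(p, 2, 2, dimnames = list(T = 0:1, S = 0:1))
  pT <- rowSums(cells)   # p_{t,+}
  pS <- colSums(cells)   # p_{+,s}
  denom <- sqrt(prod(pT) * prod(pS))
  rho <- if (denom > 0) (cells[2, 2] - pT[2] * pS[2]) / denom else NA_real_
  structure(list(cells = cells, pT = pT, pS = pS, rho = unname(rho)),
            class = "prob_table2x2")
}

#' @export
print.prob_table2x2 <- function(x, ...) {
  cat("2x2 endpoint/surrogate probability table (rows T, cols S)\n")
  print(round(x$cells, 6))
  cat("implied correlation rho =", format(x$rho, digits = 6), "\n")
  invisible(x)
}

#' Admissible correlation range for given binary margins
#'
#' The Frechet-type bounds on the point correlation \eqn{\rho} of a 2x2
#' table with success margins `p1_T`, `p1_S`, obtained by requiring all
#' four reconstructed cells to be non-negative.
#'
#' @param p1_T,p1_S success probabilities of the two margins, in (0, 1).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
binary_rho_bounds <- function(p1_T, p1_S) {
  stopifnot(p1_T > 0, p1_T < 1, p1_S > 0, p1_S < 1)
  q_T <- 1 - p1_T; q_S <- 1 - p1_S
  denom <- sqrt(p1_T * q_T * p1_S * q_S)
  c(lower = max(-p1_T * p1_S, -q_T * q_S) / denom,
    upper = min(p1_T * q_S, q_T * p1_S) / denom)
}

#' Reconstruct a 2x2 table from margins and correlation
#'
#' Builds the joint cells
#' \eqn{p_{1,1} = p_{1+}p_{+1} + \rho\sqrt{p_{1+}p_{0+}p_{+1}p_{+0}}} (and
#' the three analogous expressions with alternating signs) from the two
#' success margins and the point correlation. The construction is exact:
#' extracting \eqn{\rho} from the returned table round-trips.
#'
#' @param p1_T,p1_S success probabilities of the margins, in (0, 1).
#' @param rho point correlation, inside the admissible range given by
#'   [binary_rho_bounds()]; values outside raise an error reporting that
#'   range.
#' @return A [binary_table()].
#' @examples
#' binary_table_from_margins_rho(0.5, 0.5, 0)$cells  # all 0.25
#' @export
binary_table_from_margins_rho <- function(p1_T, p1_S, rho) {
  bounds <- binary_rho_bounds(p1_T, p1_S)
  if (rho < bounds[1] - 1e-12 || rho > bounds[2] + 1e-12) {
    stop(sprintf(
      "rho = %s outside the admissible interval [%.6f, %.6f] for margins (%s, %s)",
      format(rho), bounds[1], bounds[2], format(p1_T), format(p1_S)),
      call. = FALSE)
  }
  q_T <- 1 - p1_T; q_S <- 1 - p1_S
  d <- rho * sqrt(p1_T * q_T * p1_S * q_S)
  cells <- c(p00 = q_T * q_S + d, p10 = p1_T * q_S - d,
             p01 = q_T * p1_S - d, p11 = p1_T * p1_S + d)
  cells <- pmax(cells, 0)
  cells <- cells / sum(cells)
  binary_table(cells[1], cells[2], cells[3], cells[4])
}

#' Generalized mutual information of two binary endpoints
#'
#' Closed form for the Havrda-Charvat mutual information of a 2x2 table:
#' \deqn{I_\alpha(T,S) = \frac{1}{1-\alpha}\sum_{t}\sum_{s}
#'   \left\{ p_{t+}^\alpha\, p_{+s}^\alpha - p_{t,s}^\alpha \right\},
#'   \qquad \alpha \neq 1,}
#' with the exact Shannon mutual information (entropy decomposition
#' \eqn{H(T) + H(S) - H(T,S)}) at \eqn{\alpha = 1}. The normalized ITMA
#' divides by the ITMA of [binary_mi_max()], the largest information
#' attainable with the same margins.
#'
#' Away from the Shannon order the non-additive mutual information of this
#' family is not sign-definite: for discordant tables (e.g. cells
#' `(0.1, 0.2, 0.3, 0.4)` at \eqn{\alpha = 2}) it is slightly negative,
#' and the ITMA, its monotone transform, is then negative as well. Such
#' values indicate the absence of positive association and are returned as
#' computed rather than clamped.
#'
#' @param table a [binary_table()].
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return An object of class `"hc_mi"`.
#' @examples
#' binary_mutual_info(binary_table(0.5, 0, 0, 0.5), 2)$mi  # 0.25
#' @export
binary_mutual_info <- function(table, order) {
  stopifnot(inherits(table, "prob_table2x2"))
  order <- alpha_order(order)
  a <- order$alpha
  if (order$shannon) {
    mi <- hc_entropy_discrete(table$pT, 1) + hc_entropy_discrete(table$pS, 1) -
      hc_entropy_discrete(as.vector(table$cells), 1)
  } else {
    prod_margins <- outer(table$pT, table$pS)
    mi <- sum(prod_margins^a - table$cells^a) / (1 - a)
  }
  mi_max <- binary_mi_max(table$pT[2], table$pS[2], order)
  r2 <- 1 - exp(-2 * max(mi, 0))
  mutual_info_result(a, mi,
                     itma_normalized = r2 / (1 - exp(-2 * mi_max)),
                     normalization_kind = "binary_max",
                     allow_negative = TRUE)
}

#' Maximum attainable binary mutual information for fixed margins
#'
#' For fixed margins the joint entropy \eqn{HC_\alpha(T,S)} is monotone in
#' the table correlation \eqn{\rho}, so the information is maximised at one
#' of the two admissible boundaries of \eqn{\rho} (whichever minimises the
#' joint entropy; its sign test can be degenerate under symmetric margins,
#' so both boundaries are evaluated and the larger information is
#' returned).
#'
#' @param p1_T,p1_S success probabilities of the margins, in (0, 1).
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Scalar, the maximum \eqn{I_\alpha} over tables with the given
#'   margins.
#' @examples
#' binary_mi_max(0.5, 0.5, 2)  # 0.25
#' @export
binary_mi_max <- function(p1_T, p1_S, order) {
  order <- alpha_order(order)
  bounds <- binary_rho_bounds(p1_T, p1_S)
  mi_at <- function(rho) {
    tab <- binary_table_from_margins_rho(p1_T, p1_S, rho)
    raw_binary_mi(tab, order)
  }
  max(mi_at(bounds[1]), mi_at(bounds[2]))
}

# MI value only, without normalization (avoids infinite recursion with
# binary_mi_max).
raw_binary_mi <- function(table, order) {
  a <- order$alpha
  if (order$shannon) {
    hc_entropy_discrete(table$pT, 1) + hc_entropy_discrete(table$pS, 1) -
      hc_entropy_discrete(as.vector(table$cells), 1)
  } else {
    sum(outer(table$pT, table$pS)^a - table$cells^a) / (1 - a)
  }
}
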