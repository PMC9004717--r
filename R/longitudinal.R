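#' Visit-schedule design
#'
#' An ordered subset of a trial's visit schedule (weeks), beginning at
#' baseline week 0, defining which surrogate measurements enter a
#' surrogacy evaluation.
#'
#' @param visit_weeks strictly increasing numeric weeks including 0.
#' @return An object of class `"design_subset"`.
#' @export
design_subset <- function(visit_weeks) {
  visit_weeks <- as.numeric(visit_weeks)
  stopifnot(length(visit_weeks) >= 1, !is.unsorted(visit_weeks, strictly = TRUE))
  if (visit_weeks[1] != 0) {
    stop("a design must include the baseline week 0", call. = FALSE)
  }
  structure(list(visit_weeks = visit_weeks), class = "design_subset")
}

design_label <- function(design) paste(design$visit_weeks, collapse = ", ")

# Complete-case wide surrogate matrix for a design: rows aligned with the
# returned subjects data.frame; subjects missing any design week dropped.
design_matrix <- function(data, design) {
  stopifnot(inherits(data, "trial_data"))
  if (!inherits(design, "design_subset")) design <- design_subset(design)
  weeks <- design$visit_weeks
  missing_wk <- setdiff(weeks, data$schedule)
  if (length(missing_wk)) {
    stop("design references weeks absent from the data: ",
         paste(missing_wk, collapse = ", "), call. = FALSE)
  }
  v <- data$visits[data$visits$week %in% weeks, ]
  wide <- stats::reshape(v, idvar = "subject_id", timevar = "week",
                         direction = "wide")
  cols <- paste0("surrogate.", weeks)
  complete <- stats::complete.cases(wide[cols])
  wide <- wide[complete, , drop = FALSE]
  subjects <- data$subjects[match(wide$subject_id, data$subjects$subject_id), ]
  X <- as.matrix(wide[cols])
  colnames(X) <- paste0("wk", weeks)
  rownames(X) <- wide$subject_id
  n_dropped <- nrow(data$subjects) - nrow(subjects)
  list(X = X, subjects = subjects, n_dropped = n_dropped)
}

#' Single-index latent-probit reduction of a longitudinal surrogate
#'
#' Collapses a multivariate surrogate vector to the scalar Gaussian latent
#' model needed by [probit_mutual_info()]: a probit regression of the
#' binary endpoint on the surrogate vector defines the fitted index
#' \eqn{V = \hat\gamma' S}; the probit slope \eqn{b} of the endpoint on the
#' standardized index then gives the latent correlation
#' \eqn{\hat\rho = b/\sqrt{1+b^2}}, while \eqn{(\mu_S, \sigma_S)} are the
#' raw moments of \eqn{V} and \eqn{p_1} is the empirical endpoint rate.
#' This is the unique single-index Gaussian latent model consistent with
#' the fitted probit (a linear combination of jointly normal measurements
#' is again normal).
#'
#' @param endpoint binary 0/1 vector.
#' @param S numeric matrix of surrogate measurements (columns = visits).
#' @return A [probit_pair()] carrying the reduced model, with the fitted
#'   index in attribute `"index"`.
#' @export
single_index_reduction <- function(endpoint, S) {
  endpoint <- check_binary(endpoint, "endpoint")
  S <- as.matrix(S)
  fit <- fit_probit(endpoint, S)
  V <- drop(S %*% fit$coefficients)
  sdV <- stats::sd(V)
  p1 <- mean(endpoint)
  if (!is.finite(sdV) || sdV < 1e-12) {
    spec <- probit_pair(p1, sigma_S = 1, rho = 0, mu_S = 0)
    attr(spec, "index") <- rep(0, length(endpoint))
    return(spec)
  }
  refit <- fit_probit(endpoint, cbind(v = as.vector(scale(V))))
  b <- unname(refit$coefficients["v"])
  spec <- probit_pair(p1, sigma_S = sdV, rho = b / sqrt(1 + b^2),
                      mu_S = mean(V))
  attr(spec, "index") <- V
  spec
}

#' Trial-level arm-conditional mutual information
#'
#' The surrogacy measure \eqn{I_\alpha(T, S \mid Z)} of a longitudinal
#' continuous surrogate for a binary endpoint: within each treatment arm
#' the surrogate vector at the design's visits is reduced to a scalar
#' latent-probit model ([single_index_reduction()]), scored with the
#' closed-form [probit_mutual_info()], and the two arms are averaged with
#' their empirical weights,
#' \eqn{I_\alpha(T,S|Z) = I_\alpha(T,S|Z{=}1)P(Z{=}1) +
#' I_\alpha(T,S|Z{=}0)P(Z{=}0)}.
#' Subjects missing any design visit are excluded (complete case).
#'
#' @param data a [trial_dataset()].
#' @param design a [design_subset()] or numeric week vector.
#' @param order entropy order, an [alpha_order] or a positive number.
#' @return Scalar mutual information, with per-arm values, weights and
#'   dropped-subject count in attribute `"detail"`.
#' @export
arm_conditional_mi <- function(data, design, order) {
  order <- alpha_order(order)
  dm <- design_matrix(data, design)
  arms <- dm$subjects$arm
  per_arm <- numeric(2)
  for (z in 0:1) {
    idx <- arms == z
    if (!any(idx)) stop("arm ", z, " is empty", call. = FALSE)
    y <- dm$subjects$endpoint[idx]
    if (length(unique(y)) < 2L) {
      stop("endpoint is constant within arm ", z,
           "; arm-conditional information is undefined", call. = FALSE)
    }
    spec <- single_index_reduction(y, dm$X[idx, , drop = FALSE])
    per_arm[z + 1] <- probit_mutual_info(spec, order)$mi
  }
  w <- c(mean(arms == 0), mean(arms == 1))
  mi <- sum(w * per_arm)
  attr(mi, "detail") <- list(per_arm = per_arm, weights = w,
                             n_dropped = dm$n_dropped)
  mi
}

#' Prentice-criterion conditional mutual information
#'
#' \eqn{I_\alpha(T, Z \mid S)}: the residual dependence between endpoint
#' and treatment after conditioning on the surrogate trajectory. A valid
#' surrogate in Prentice's sense makes \eqn{Z \to S \to T} Markov, hence
#' this quantity approximately zero. A bivariate probit of \eqn{(T, Z)} on
#' the design's surrogate vector supplies the conditional cell and margin
#' probabilities; the outer expectation over \eqn{S} is the empirical mean
#' over observed subject trajectories of
#' \deqn{\frac{1}{1-\alpha}\sum_t\sum_z\left\{[p(T{=}t|S)]^\alpha
#'   [p(Z{=}z|S)]^\alpha - [p(T{=}t,Z{=}z|S)]^\alpha\right\}}
#' (with the usual entropy-decomposition form at \eqn{\alpha = 1}).
#'
#' @inheritParams arm_conditional_mi
#' @return Scalar conditional mutual information; the fitted bivariate
#'   probit is attached as attribute `"fit"`.
#' @export
prentice_conditional_mi <- function(data, design, order) {
  order <- alpha_order(order)
  dm <- design_matrix(data, design)
  fit <- fit_bivariate_probit(dm$subjects$endpoint, dm$subjects$arm, dm$X)
  mi <- prentice_mi_from_fit(fit, dm$X, order)
  attr(mi, "fit") <- fit
  mi
}

# inner Eq-(12)-style computation given a fitted bivariate probit
prentice_mi_from_fit <- function(fit, X, order) {
  a <- order$alpha
  cells <- biprobit_cells(fit, X)           # p00 p10 p01 p11, (T, Z)
  pT1 <- cells[, "p10"] + cells[, "p11"]
  pZ1 <- cells[, "p01"] + cells[, "p11"]
  pT <- cbind(1 - pT1, pT1)
  pZ <- cbind(1 - pZ1, pZ1)
  if (order$shannon) {
    xlx <- function(p) ifelse(p > 0, p * log(p), 0)
    per <- -rowSums(xlx(pT)) - rowSums(xlx(pZ)) + rowSums(xlx(cells))
  } else {
    prod_margins <- cbind(pT[, 1] * pZ[, 1], pT[, 2] * pZ[, 1],
                          pT[, 1] * pZ[, 2], pT[, 2] * pZ[, 2])
    per <- (rowSums(prod_margins^a) - rowSums(cells^a)) / (1 - a)
  }
  max(mean(per), 0)
}

#' Permutation null for the Prentice measure
#'
#' Re-computes [prentice_conditional_mi()] after permuting the endpoint
#' within each treatment arm, which breaks the surrogate-endpoint link
#' while preserving arm sizes and arm-specific endpoint rates. The
#' resulting distribution calibrates what "approximately zero" means for
#' the Prentice check on a given dataset and design.
#'
#' @inheritParams arm_conditional_mi
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return Numeric vector of `n_perm` null values.
#' @export
prentice_permutation_null <- function(data, design, order, n_perm = 200,
                                      seed = 20220131L) {
  order <- alpha_order(order)
  dm <- design_matrix(data, design)
  arms <- dm$subjects$arm
  y <- dm$subjects$endpoint
  withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- y
      for (z in 0:1) {
        idx <- which(arms == z)
        yp[idx] <- y[sample(idx)]
      }
      fit <- fit_bivariate_probit(yp, arms, dm$X)
      prentice_mi_from_fit(fit, dm$X, order)
    }, numeric(1))
  })
}

#' Evaluate a grid of designs and entropy orders
#'
#' The full design-comparison workflow: for every visit-schedule design
#' and every entropy order, computes the trial-level surrogacy measure
#' \eqn{I_\alpha(T,S|Z)} with its ITMA and the Prentice measure
#' \eqn{I_\alpha(T,Z|S)} with its ITMA. A failing design is recorded in
#' its rows' `error` column rather than aborting the sweep. Deterministic
#' given the data and settings.
#'
#' @param data a [trial_dataset()].
#' @param designs list of [design_subset()]s or numeric week vectors.
#' @param alphas numeric vector of entropy orders.
#' @return A `"surrogacy_report"`: a data.frame with columns `design`,
#'   `alpha`, `mi_TS_given_Z`, `itma_TS`, `mi_TZ_given_S`, `itma_TZ`,
#'   `error`, and per-arm counts in attribute `"meta"`.
#' @export
design_sweep <- function(data, designs, alphas) {
  stopifnot(inherits(data, "trial_data"), length(designs) >= 1,
            length(alphas) >= 1)
  rows <- list()
  for (d in designs) {
    design <- if (inherits(d, "design_subset")) d else design_subset(d)
    lab <- design_label(design)
    for (a in alphas) {
      row <- data.frame(design = lab, alpha = a,
                        mi_TS_given_Z = NA_real_, itma_TS = NA_real_,
                        mi_TZ_given_S = NA_real_, itma_TZ = NA_real_,
                        error = NA_character_)
      res <- tryCatch({
        mi_ts <- arm_conditional_mi(data, design, a)
        mi_tz <- prentice_conditional_mi(data, design, a)
        row$mi_TS_given_Z <- as.numeric(mi_ts)
        row$itma_TS <- itma_from_mi(as.numeric(mi_ts))
        row$mi_TZ_given_S <- as.numeric(mi_tz)
        row$itma_TZ <- itma_from_mi(as.numeric(mi_tz))
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "meta") <- list(
    n_control = sum(data$subjects$arm == 0),
    n_treatment = sum(data$subjects$arm == 1),
    alphas = alphas, seed = data$seed)
  class(report) <- c("surrogacy_report", "data.frame")
  report
}

#' @export
print.surrogacy_report <- function(x, digits = 4, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Surrogacy report: %d designs x %d orders (control %d, treatment %d)\n",
              length(unique(x$design)), length(meta$alphas),
              meta$n_control, meta$n_treatment))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
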