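#' Univariate probit regression by maximum likelihood
#'
#' Fits \eqn{P(Y = 1 \mid x) = \Phi(\beta_0 + x'\beta)} via iteratively
#' reweighted least squares ([stats::glm()] with a probit link), with
#' explicit checks for the degenerate cases that break downstream surrogacy
#' computations: a one-class outcome, a rank-deficient design, and perfect
#' separation (under which the MLE does not exist).
#'
#' @param outcome binary 0/1 vector.
#' @param predictors numeric matrix (one column per predictor, no
#'   intercept column) or NULL for an intercept-only model.
#' @return An object of class `"probit_fit"`: intercept, named coefficient
#'   vector, standard errors, covariance, log-likelihood and convergence
#'   flag.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, pnorm(-0.3 + 0.8 * x))
#' fit_probit(y, cbind(x = x))
#' @export
fit_probit <- function(outcome, predictors = NULL) {
  outcome <- check_binary(outcome, "outcome")
  if (length(unique(outcome)) < 2L) {
    stop("outcome has a single class; probit fit is undefined", call. = FALSE)
  }
  X <- build_design(predictors, length(outcome))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, outcome, family = stats::binomial(link = "probit"),
                   control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- fit$fitted.values
  boundary <- mu < 1e-12 | mu > 1 - 1e-12
  if (sep_warn && any(boundary) && all((mu > 0.5) == (outcome == 1))) {
    cf <- fit$coefficients[-1]
    worst <- if (length(cf)) names(which.max(abs(cf) * apply(X[, -1, drop = FALSE], 2, stats::sd)))
             else "(intercept)"
    stop("perfect separation detected (predictor '", worst,
         "'): probit MLE does not exist", call. = FALSE)
  }
  eta <- fit$linear.predictors
  ll <- sum(outcome * stats::pnorm(eta, log.p = TRUE) +
              (1 - outcome) * stats::pnorm(-eta, log.p = TRUE))
  # score at the solution
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  score <- crossprod(X, (outcome - mu_c) * stats::dnorm(eta) /
                       (mu_c * (1 - mu_c)))
  w <- stats::dnorm(eta)^2 / (mu_c * (1 - mu_c))
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  cf <- fit$coefficients
  structure(list(
    intercept = unname(cf[1]), coefficients = cf[-1],
    se = sqrt(diag(vc)), vcov = vc,
    converged = fit$converged &&
      max(abs(score)) < 1e-6 * max(1, length(outcome) / 100),
    loglik = ll, fitted = mu, linear_predictor = eta, n = length(outcome)),
    class = "probit_fit")
}

check_binary <- function(y, what) {
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) {
    stop("'", what, "' must be coded 0/1", call. = FALSE)
  }
  y
}

build_design <- function(predictors, n) {
  if (is.null(predictors)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
    return(X)
  }
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind("(intercept)" = 1, X)
  if (nrow(X) != n) stop("predictor rows must match outcome length", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("predictor matrix is rank deficient", call. = FALSE)
  }
  X
}

#' Bivariate probit regression by maximum likelihood
#'
#' Joint model for two binary outcomes \eqn{(T, Z)} whose latent normals
#' share predictors and have correlation \eqn{\rho}:
#' each cell probability is a bivariate normal CDF,
#' \eqn{P(T = t, Z = z \mid x) = \Phi_2(q_t x'\beta_T,\; q_z x'\beta_Z,\;
#' q_t q_z \rho)} with \eqn{q_u = 2u - 1}. The likelihood (written here,
#' not delegated) is maximised by BFGS with its analytic gradient over
#' \eqn{(\beta_T, \beta_Z, \mathrm{atanh}\,\rho)}, starting from the two
#' univariate probit fits with \eqn{\rho = 0}, with up to 3 jittered
#' restarts. Cell probabilities are floored at `1e-300` inside the
#' log-likelihood.
#'
#' @param outcome_T,outcome_Z binary 0/1 vectors.
#' @param predictors numeric matrix shared by both equations (no intercept
#'   column), or NULL.
#' @return An object of class `"biprobit_fit"` with intercepts, coefficient
#'   vectors, `rho_latent` in \eqn{(-1, 1)}, standard errors (delta method
#'   for \eqn{\rho}), log-likelihood, convergence flag and a
#'   `rho_boundary` warning flag when \eqn{|\hat\rho| > 0.99}.
#' @export
fit_bivariate_probit <- function(outcome_T, outcome_Z, predictors = NULL) {
  yT <- check_binary(outcome_T, "outcome_T")
  yZ <- check_binary(outcome_Z, "outcome_Z")
  if (length(yT) != length(yZ)) stop("outcome lengths differ", call. = FALSE)
  if (length(unique(yT)) < 2L || length(unique(yZ)) < 2L) {
    stop("both outcomes must have two classes", call. = FALSE)
  }
  X <- build_design(predictors, length(yT))
  p <- ncol(X)
  qT <- 2 * yT - 1
  qZ <- 2 * yZ - 1

  negll <- function(theta) {
    lpT <- drop(X %*% theta[1:p])
    lpZ <- drop(X %*% theta[(p + 1):(2 * p)])
    rho <- tanh(theta[2 * p + 1])
    pr <- pbvnorm(qT * lpT, qZ * lpZ, qT * qZ * rho)
    -sum(log(pmax(pr, 1e-300)))
  }
  grad <- function(theta) {
    lpT <- drop(X %*% theta[1:p])
    lpZ <- drop(X %*% theta[(p + 1):(2 * p)])
    eta <- theta[2 * p + 1]
    rho <- tanh(eta)
    w1 <- qT * lpT; w2 <- qZ * lpZ; r <- qT * qZ * rho
    pr <- pmax(pbvnorm(w1, w2, r), 1e-300)
    den <- sqrt(pmax(1 - r^2, 1e-12))
    dP_dlpT <- qT * stats::dnorm(w1) * stats::pnorm((w2 - r * w1) / den)
    dP_dlpZ <- qZ * stats::dnorm(w2) * stats::pnorm((w1 - r * w2) / den)
    phi2 <- exp(-(w1^2 - 2 * r * w1 * w2 + w2^2) / (2 * den^2)) /
      (2 * pi * den)
    dP_drho <- qT * qZ * phi2
    gT <- crossprod(X, dP_dlpT / pr)
    gZ <- crossprod(X, dP_dlpZ / pr)
    g_eta <- sum(dP_drho / pr) * (1 - rho^2)
    -c(gT, gZ, g_eta)
  }

  fT <- fit_probit(yT, predictors)
  fZ <- fit_probit(yZ, predictors)
  start <- c(fT$intercept, fT$coefficients, fZ$intercept, fZ$coefficients, 0)

  best <- NULL
  set_jitter <- function(k) if (k == 0) 0 else stats::rnorm(2 * p + 1, 0, 0.05 * k)
  for (attempt in 0:3) {
    th0 <- start + set_jitter(attempt)
    opt <- tryCatch(
      stats::optim(th0, negll, grad, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # Newton polish: BFGS stops on function change and can leave a small
    # residual gradient when predictors are badly scaled.
    par <- opt$par
    val <- opt$value
    for (it in 1:10) {
      g <- grad(par)
      if (max(abs(g)) < 1e-8) break
      H <- tryCatch(stats::optimHess(par, negll, grad), error = function(e) NULL)
      step <- if (!is.null(H)) tryCatch(solve(H, g), error = function(e) NULL) else NULL
      if (is.null(step)) break
      cand <- par - step
      vc <- negll(cand)
      if (!is.finite(vc) || vc > val + 1e-8) break
      par <- cand; val <- vc
    }
    gn <- max(abs(grad(par)))
    if (is.null(best) || val < best$value) {
      best <- list(par = par, value = val, gnorm = gn)
    }
    if (gn < 1e-6 * max(1, length(yT) / 100)) break
  }
  if (is.null(best)) stop("bivariate probit optimisation failed", call. = FALSE)
  gn_tol <- 1e-6 * max(1, length(yT) / 100)
  if (best$gnorm >= gn_tol) {
    stop(sprintf(
      "bivariate probit did not converge after restarts (best loglik %.6f, gradient norm %.2e)",
      -best$value, best$gnorm), call. = FALSE)
  }
  theta <- best$par
  rho <- tanh(theta[2 * p + 1])
  H <- tryCatch(stats::optimHess(theta, negll, grad), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, 2 * p + 1)
  se_rho <- se[2 * p + 1] * (1 - rho^2)
  nms <- colnames(X)[-1]
  structure(list(
    intercept_T = unname(theta[1]),
    gamma_T = stats::setNames(unname(theta[seq_len(p - 1) + 1]), nms),
    intercept_Z = unname(theta[p + 1]),
    gamma_Z = stats::setNames(unname(theta[(p + 1) + seq_len(p - 1)]), nms),
    rho_latent = unname(rho),
    se = stats::setNames(c(se[seq_len(2 * p)], se_rho),
                         c(paste0("T:", colnames(X)), paste0("Z:", colnames(X)), "rho")),
    vcov = vc,
    converged = TRUE,
    rho_boundary = abs(rho) > 0.99,
    loglik = -best$value, n = length(yT),
    design = X),
    class = "biprobit_fit")
}

#' Conditional cell probabilities from a bivariate probit fit
#'
#' The four probabilities \eqn{P(T = t, Z = z \mid x)} implied by a fitted
#' bivariate probit at one predictor row, from the bivariate normal CDF
#' with the fitted latent correlation. The cells sum to 1 and their margins
#' reproduce the two univariate linear predictors; at \eqn{\hat\rho = 0}
#' each cell factorises into the product of its margins.
#'
#' @param fit a `"biprobit_fit"`.
#' @param predictors_row numeric vector of predictor values (no intercept).
#' @return Named length-4 probability vector `(p00, p10, p01, p11)`
#'   (first index \eqn{T}, second \eqn{Z}).
#' @export
conditional_cell_probs <- function(fit, predictors_row = numeric(0)) {
  stopifnot(inherits(fit, "biprobit_fit"))
  drop(biprobit_cells(fit, matrix(predictors_row, nrow = 1)))
}

# Vectorised cell probabilities; X without intercept, one row per subject.
# Returns an n x 4 matrix with columns p00, p10, p01, p11.
biprobit_cells <- function(fit, X) {
  X <- as.matrix(X)
  lpT <- fit$intercept_T + drop(X %*% fit$gamma_T)
  lpZ <- fit$intercept_Z + drop(X %*% fit$gamma_Z)
  p11 <- pbvnorm(lpT, lpZ, fit$rho_latent)
  pT1 <- stats::pnorm(lpT)
  pZ1 <- stats::pnorm(lpZ)
  cells <- cbind(p00 = 1 - pT1 - pZ1 + p11, p10 = pT1 - p11,
                 p01 = pZ1 - p11, p11 = p11)
  cells <- pmax(cells, 0)
  cells / rowSums(cells)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit regression (n =", x$n, ")\n")
  print(round(c("(intercept)" = x$intercept, x$coefficients), 4))
  cat("loglik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
print.biprobit_fit <- function(x, ...) {
  cat("Bivariate probit regression (n =", x$n, ")\n")
  cat("T equation:\n")
  print(round(c("(intercept)" = x$intercept_T, x$gamma_T), 4))
  cat("Z equation:\n")
  print(round(c("(intercept)" = x$intercept_Z, x$gamma_Z), 4))
  cat("latent correlation rho =", format(x$rho_latent, digits = 4),
      if (isTRUE(x$rho_boundary)) "(near boundary)" else "", "\n")
  cat("loglik:", format(x$loglik), "\n")
  invisible(x)
}

#' Serialize a probit or bivariate probit fit to JSON
#'
#' Writes parameter names, estimates, standard errors, log-likelihood and
#' convergence metadata as a plain JSON document.
#'
#' @param fit a `"probit_fit"` or `"biprobit_fit"`.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, c("probit_fit", "biprobit_fit")))
  payload <- if (inherits(fit, "probit_fit")) {
    list(model = "probit",
         estimates = as.list(c("(intercept)" = fit$intercept, fit$coefficients)),
         se = as.list(fit$se), loglik = fit$loglik, converged = fit$converged,
         n = fit$n)
  } else {
    list(model = "bivariate_probit",
         estimates = as.list(c(
           "T:(intercept)" = fit$intercept_T,
           stats::setNames(fit$gamma_T, paste0("T:", names(fit$gamma_T))),
           "Z:(intercept)" = fit$intercept_Z,
           stats::setNames(fit$gamma_Z, paste0("Z:", names(fit$gamma_Z))),
           rho = fit$rho_latent)),
         se = as.list(fit$se), loglik = fit$loglik, converged = fit$converged,
         rho_boundary = fit$rho_boundary, n = fit$n)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
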