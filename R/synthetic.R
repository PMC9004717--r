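#' Configuration for the synthetic longitudinal trial generator
#'
#' Parameters of a two-arm trial with a repeatedly measured continuous
#' surrogate and one binary endpoint per subject. The surrogate follows
#' \deqn{S_{ij} = \mu_S + \alpha_1 Z_i + \alpha_2 t_j + \alpha_3 Z_i t_j
#'   + \beta_j T_i + \epsilon_{S,ij},}
#' with compound-symmetry correlation among a subject's visit residuals.
#' The endpoint is generated from the latent-probit model
#' \eqn{U_i = a_0 + a_1 Z_i + a_2 X_i + e_i}, \eqn{e_i \sim N(0,1)},
#' \eqn{T_i = 1\{U_i \ge 0\}}, where \eqn{X_i} is the standardized
#' subject-level mean of the pre-endpoint surrogate trajectory. This makes
#' the generator an exact instance of the latent-probit family, so
#' population mutual-information values are computable; setting `a1 = 0`
#' yields a Markov (\eqn{Z \to S \to T}) generator.
#'
#' Defaults emulate a two-arm progressive-MS imaging trial: 104 control and
#' 99 treated subjects, visits at weeks 0/24/48/72/96, brain-parenchymal-
#' fraction-like surrogate (mean 0.8023, SD 0.0301, within-subject
#' correlation 0.9, per-24-week slopes \eqn{-0.0008} control and
#' \eqn{-0.0004} treated) and endpoint response rates near 48% vs 71%.
#'
#' @param n_control,n_treatment arm sizes.
#' @param visit_weeks visit schedule in weeks, starting at baseline 0.
#' @param mu_S baseline surrogate mean (control arm).
#' @param alpha1 arm effect on the surrogate.
#' @param alpha2 time slope per week.
#' @param alpha3 arm-by-time interaction per week.
#' @param beta per-visit additive endpoint effect on the surrogate
#'   (length of `visit_weeks`).
#' @param sd_resid marginal residual SD of the surrogate.
#' @param corr_within compound-symmetry correlation in \eqn{[0, 1)}.
#' @param a0,a1,a2 latent endpoint model: intercept, direct treatment
#'   effect, and coefficient on the standardized surrogate index.
#' @param seed integer seed recorded in the dataset and used by
#'   [generate_trial()].
#' @return An object of class `"trial_config"` (a validated list).
#' @export
trial_config <- function(n_control = 104L, n_treatment = 99L,
                         visit_weeks = c(0, 24, 48, 72, 96),
                         mu_S = 0.8023, alpha1 = 0.0017,
                         alpha2 = -0.0008 / 24, alpha3 = 0.0004 / 24,
                         beta = rep(0, length(visit_weeks)),
                         sd_resid = 0.0301, corr_within = 0.9,
                         a0 = -0.112, a1 = 1.35, a2 = 2,
                         seed = 20220131L) {
  stopifnot(n_control >= 1, n_treatment >= 1,
            length(visit_weeks) >= 1, !is.unsorted(visit_weeks, strictly = TRUE),
            visit_weeks[1] == 0,
            length(beta) == length(visit_weeks),
            sd_resid > 0, corr_within >= 0, corr_within < 1)
  if (seed >= 2^31) stop("seed must be a 32-bit integer", call. = FALSE)
  structure(list(n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 visit_weeks = visit_weeks, mu_S = mu_S,
                 alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 beta = beta, sd_resid = sd_resid, corr_within = corr_within,
                 a0 = a0, a1 = a1, a2 = a2, seed = as.integer(seed)),
            class = "trial_config")
}

#' Longitudinal trial dataset
#'
#' Validating constructor for the container consumed by the surrogacy
#' pipeline: one binary endpoint and one arm per subject, long-format
#' surrogate visits on a common schedule, no duplicated (subject, week)
#' pair.
#'
#' @param subjects data.frame with columns `subject_id`, `arm` (0/1),
#'   `endpoint` (0/1).
#' @param visits data.frame with columns `subject_id`, `week`, `surrogate`.
#' @param seed optional integer recorded for provenance.
#' @return An object of class `"trial_data"`.
#' @export
trial_dataset <- function(subjects, visits, seed = NA_integer_) {
  req_s <- c("subject_id", "arm", "endpoint")
  req_v <- c("subject_id", "week", "surrogate")
  if (!all(req_s %in% names(subjects))) {
    stop("'subjects' needs columns: ", paste(req_s, collapse = ", "), call. = FALSE)
  }
  if (!all(req_v %in% names(visits))) {
    stop("'visits' needs columns: ", paste(req_v, collapse = ", "), call. = FALSE)
  }
  subjects$arm <- check_binary(subjects$arm, "arm")
  subjects$endpoint <- check_binary(subjects$endpoint, "endpoint")
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicated subject_id in 'subjects'", call. = FALSE)
  }
  dup <- duplicated(visits[c("subject_id", "week")])
  if (any(dup)) {
    d <- visits[dup, , drop = FALSE][1, ]
    stop("duplicate visit row: subject ", d$subject_id, ", week ", d$week,
         call. = FALSE)
  }
  if (!all(visits$subject_id %in% subjects$subject_id)) {
    stop("visit rows reference unknown subjects", call. = FALSE)
  }
  if (!is.numeric(visits$surrogate) || any(!is.finite(visits$surrogate))) {
    stop("surrogate values must be finite numbers", call. = FALSE)
  }
  structure(list(subjects = subjects[req_s],
                 visits = visits[req_v],
                 schedule = sort(unique(visits$week)),
                 seed = seed),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  n <- table(factor(x$subjects$arm, levels = 0:1))
  cat("Longitudinal trial dataset:", nrow(x$subjects), "subjects",
      sprintf("(control %d / treatment %d),", n[1], n[2]),
      nrow(x$visits), "visit rows\n")
  cat("schedule (weeks):", paste(x$schedule, collapse = ", "), "\n")
  rates <- tapply(x$subjects$endpoint, x$subjects$arm, mean)
  cat(sprintf("endpoint rate: control %.3f, treatment %.3f\n",
              rates["0"], rates["1"]))
  invisible(x)
}

#' Generate a synthetic longitudinal trial
#'
#' Simulates a [trial_config()] model: multivariate normal surrogate
#' trajectories with compound-symmetry residuals, endpoint drawn from the
#' latent-probit model on the standardized surrogate index, and the
#' per-visit endpoint effect `beta` added to the trajectories of
#' responders. Deterministic given `config$seed`.
#'
#' @param config a [trial_config()].
#' @return A [trial_dataset()].
#' @examples
#' d <- generate_trial(trial_config(n_control = 30, n_treatment = 30))
#' print(d)
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  withr_seed(config$seed, {
    n <- config$n_control + config$n_treatment
    K <- length(config$visit_weeks)
    Z <- rep(c(0, 1), c(config$n_control, config$n_treatment))
    ids <- sprintf("S%04d", seq_len(n))
    Sigma <- config$sd_resid^2 *
      ((1 - config$corr_within) * diag(K) + config$corr_within)
    ch <- tryCatch(chol(Sigma),
                   error = function(e) stop("invalid residual covariance: ",
                                            conditionMessage(e), call. = FALSE))
    E <- matrix(stats::rnorm(n * K), n, K) %*% ch
    t_j <- config$visit_weeks
    mean_mat <- config$mu_S + config$alpha1 * Z +
      outer(Z * 0 + 1, config$alpha2 * t_j) + outer(Z, config$alpha3 * t_j)
    S0 <- mean_mat + E
    X <- as.vector(scale(rowMeans(S0)))
    U <- config$a0 + config$a1 * Z + config$a2 * X + stats::rnorm(n)
    T_i <- as.numeric(U >= 0)
    S <- S0 + outer(T_i, config$beta)
    subjects <- data.frame(subject_id = ids, arm = Z, endpoint = T_i)
    visits <- data.frame(subject_id = rep(ids, each = K),
                         week = rep(t_j, n),
                         surrogate = as.vector(t(S)))
    trial_dataset(subjects, visits, seed = config$seed)
  })
}

#' Generate a trial in which the surrogate fully mediates treatment
#'
#' Identical to [generate_trial()] except that the direct treatment effect
#' on the endpoint is forced to zero (`a1 = 0`), so that
#' \eqn{Z \to S \to T} is Markov by construction: conditioning on the
#' surrogate trajectory, endpoint and treatment are independent. Arm
#' endpoint rates can still differ when the treatment shifts the surrogate
#' (`alpha1`, `alpha3`), since that effect is mediated through the index.
#'
#' @param config a [trial_config()]; its `a1` is ignored.
#' @return A [trial_dataset()].
#' @export
generate_markov_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  config$a1 <- 0
  generate_trial(config)
}

# run expr with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Heavy-tailed density with a standard normal core
#'
#' The piecewise density
#' \deqn{f(x) = \phi(x) \text{ for } |x| \le c_1, \qquad
#'   f(x) = \frac{c_2}{|x| (\log|x|)^2} \text{ for } |x| > c_1,}
#' whose Shannon (differential) entropy is infinite while its
#' Havrda-Charvat entropy of any order \eqn{\alpha > 1} is finite (the
#' density is bounded by \eqn{\phi(0)}). The constants are the unique
#' solution of continuity at \eqn{|x| = c_1} together with total
#' probability one; see [solve_heavy_tail_constants()].
#'
#' @param c1,c2 junction point and tail constant.
#' @return An object of class `"heavy_tail_density"`: `c1`, `c2`, the
#'   vectorised density `pdf`, and `spec`, a [density_spec] usable with
#'   [hc_entropy_continuous()].
#' @export
heavy_tail_density <- function(c1, c2) {
  stopifnot(c1 > 1, c2 > 0)
  pdf <- function(x) {
    ifelse(abs(x) <= c1, stats::dnorm(x), c2 / (abs(x) * log(abs(x))^2))
  }
  structure(list(c1 = c1, c2 = c2, pdf = pdf,
                 spec = density_spec(pdf, c(-Inf, Inf), bound = stats::dnorm(0))),
            class = "heavy_tail_density")
}

#' Solve for the heavy-tail density constants
#'
#' Root-finds the junction point \eqn{c_1 > 1} of [heavy_tail_density()]
#' from the combined continuity/normalization equation
#' \deqn{\phi(c_1)\, c_1 \log(c_1) = 1 - \Phi(c_1)}
#' (continuity \eqn{\phi(c_1) = c_2 / (c_1 (\log c_1)^2)} and tail mass
#' \eqn{2 c_2 / \log c_1 = 2(1 - \Phi(c_1))}), then sets
#' \eqn{c_2 = (1 - \Phi(c_1)) \log(c_1)}. Residuals of both defining
#' equations are below `1e-10` and the returned density integrates to one
#' to the same tolerance. The solution is \eqn{c_1 \approx 1.44},
#' \eqn{c_2 \approx 0.027}.
#'
#' @return A [heavy_tail_density()] with the solved constants.
#' @examples
#' ht <- solve_heavy_tail_constants()
#' round(ht$c1, 2); round(ht$c2, 3)
#' @export
solve_heavy_tail_constants <- function() {
  g <- function(c1) stats::dnorm(c1) * c1 * log(c1) - (1 - stats::pnorm(c1))
  root <- stats::uniroot(g, c(1.05, 5), tol = 1e-14)
  if (abs(root$estim.prec) > 1e-8 && abs(g(root$root)) > 1e-10) {
    stop("root finder failed to locate the junction point", call. = FALSE)
  }
  c1 <- root$root
  c2 <- (1 - stats::pnorm(c1)) * log(c1)
  ht <- heavy_tail_density(c1, c2)
  # defensive residual checks: continuity and total mass
  cont <- stats::dnorm(c1) - c2 / (c1 * log(c1)^2)
  mass <- (2 * stats::pnorm(c1) - 1) + 2 * c2 / log(c1) - 1
  if (abs(cont) > 1e-10 || abs(mass) > 1e-10) {
    stop("heavy-tail constants failed residual checks", call. = FALSE)
  }
  ht
}
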