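#' Control parameters for the internal GLM fitter
#'
#' @param epsilon Relative deviance-change convergence tolerance for IRLS.
#' @param maxit Maximum number of IRLS iterations.
#' @param eta_cap Cap on the absolute linear predictor; fits that hit the cap
#'   (perfect or quasi-perfect separation) are returned with
#'   `converged = FALSE` rather than raising an error, because pure nodes are
#'   expected in deep trees.
#' @param prob_eps Fitted probabilities are clamped to
#'   `[prob_eps, 1 - prob_eps]` before likelihood evaluation so that pure
#'   nodes never produce `NaN`.
#' @return A list of class `glm_control`.
#' @export
glm_control <- function(epsilon = 1e-8, maxit = 50L, eta_cap = 30,
                        prob_eps = 1e-10) {
  stopifnot(epsilon > 0, maxit >= 1, eta_cap > 0, prob_eps > 0, prob_eps < 0.5)
  structure(list(epsilon = epsilon, maxit = as.integer(maxit),
                 eta_cap = eta_cap, prob_eps = prob_eps),
            class = "glm_control")
}

clamp_prob <- function(mu, eps = 1e-10) pmin(pmax(mu, eps), 1 - eps)

#' Binomial deviance of fitted probabilities
#'
#' Computes `-2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))`.  For a
#' binary outcome the saturated log-likelihood is zero, so this equals twice
#' the gap to saturation.  Probabilities are clamped away from 0 and 1 so a
#' conflicting observation in a pure node yields a large finite value, never
#' `NaN`.
#'
#' @param y Binary (0/1) outcome vector.
#' @param mu Vector of fitted probabilities.
#' @param weights Optional nonnegative case weights (default all one).
#' @param eps Clamping constant for `mu`.
#' @return Nonnegative scalar deviance.
#' @export
binomial_deviance <- function(y, mu, weights = NULL, eps = 1e-10) {
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  mu <- clamp_prob(mu, eps)
  ll <- y * log(mu) + (1 - y) * log(1 - mu)
  if (!is.null(weights)) ll <- weights * ll
  -2 * sum(ll)
}

#' Fit a logistic GLM with a fixed offset
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares.  The design matrix is used exactly as supplied: no intercept is
#' ever added implicitly, because in partially linear tree models the leaf
#' indicator columns play the role of per-leaf intercepts and an extra
#' constant column would be collinear with them.  The offset enters the
#' linear predictor with coefficient fixed at one.
#'
#' Separation is handled by capping the linear predictor at
#' `control$eta_cap` in absolute value; a fit that ends on the cap is
#' returned with `converged = FALSE` instead of erroring, since pure leaves
#' are routine in maximal trees.
#'
#' @param y Binary (0/1) outcome vector.
#' @param design Numeric matrix of predictors (may have zero columns).
#' @param offset Optional per-observation offset (default zero).
#' @param weights Optional nonnegative case weights.
#' @param control A [glm_control()] list.
#' @param start Optional starting coefficient vector (warm start); the
#'   maximum-likelihood solution is unique, so this affects speed only.
#' @return A list of class `pltr_glm` with elements `coefficients`,
#'   `loglik`, `deviance`, `fitted_means`, `linear_predictor`, `converged`
#'   and `n_iter`.
#' @examples
#' y <- rep(c(1, 0), c(3, 7))
#' f <- fit_glm(y, matrix(1, 10, 1))
#' f$coefficients            # logit(0.3)
#' @export
fit_glm <- function(y, design, offset = NULL, weights = NULL,
                    control = glm_control(), start = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (is.null(design)) design <- matrix(numeric(0), n, 0)
  design <- as.matrix(design)
  if (nrow(design) != n) stop("design row count must match outcome length")
  if (is.null(offset)) offset <- rep(0, n)
  if (length(offset) != n) stop("offset length must match outcome length")
  if (any(!is.finite(offset))) stop("offset must be finite")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0)) stop("weights must be nonnegative")

  p <- ncol(design)
  beta <- if (!is.null(start) && length(start) == p && all(is.finite(start)))
    as.numeric(start) else rep(0, p)
  eta_raw <- offset + if (p) drop(design %*% beta) else 0
  eta <- pmin(pmax(eta_raw, -control$eta_cap), control$eta_cap)
  mu <- clamp_prob(stats::plogis(eta), control$prob_eps)
  dev <- binomial_deviance(y, mu, w, control$prob_eps)
  converged <- FALSE
  it <- 0L

  if (p > 0) {
    for (it in seq_len(control$maxit)) {
      wirls <- w * mu * (1 - mu)
      z <- (eta - offset) + (y - mu) / (mu * (1 - mu))
      fit <- stats::lm.wfit(design, z, wirls)
      b <- fit$coefficients
      b[is.na(b)] <- 0            # rank-deficient columns contribute nothing
      eta_raw <- offset + drop(design %*% b)
      eta <- pmin(pmax(eta_raw, -control$eta_cap), control$eta_cap)
      mu <- clamp_prob(stats::plogis(eta), control$prob_eps)
      dev_new <- binomial_deviance(y, mu, w, control$prob_eps)
      beta <- b
      if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < control$epsilon) {
        dev <- dev_new
        converged <- TRUE
        break
      }
      dev <- dev_new
    }
  } else {
    converged <- TRUE
  }
  # boundary fits (separation, or an iterate pushed onto the probability
  # clamp) are flagged: the estimates are usable but not an interior MLE
  if (any(abs(eta_raw) > control$eta_cap) ||
      any(mu <= control$prob_eps | mu >= 1 - control$prob_eps))
    converged <- FALSE

  names(beta) <- colnames(design)
  ll <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  structure(list(coefficients = beta, loglik = ll, deviance = dev,
                 fitted_means = mu, linear_predictor = eta,
                 converged = converged, n_iter = it),
            class = "pltr_glm")
}

#' @export
print.pltr_glm <- function(x, ...) {
  cat("Logistic GLM fit:", length(x$coefficients), "coefficients,",
      "deviance", format(x$deviance, digits = 6),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}
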