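# Generalized likelihood-ratio test of the confounder-only null against the
# selected partially linear tree model.  Because the tree is estimated
# nonparametrically, the statistic does not follow the naive chi-squared law
# with (leaves - 1) degrees of freedom; following the generalized
# likelihood-ratio theory for models with nonparametric components, a scaled
# chi-squared law m * Lambda ~ chisq(b) is assumed and (m, b) are estimated
# by a conditional parametric bootstrap under the fitted null.

#' Likelihood-ratio statistic between two nested GLM fits
#'
#' `Lambda = 2 * (loglik_H1 - loglik_H0)`, nonnegative for nested designs.
#' Tiny negative values (numerical noise) are clamped to zero; a negative
#' value beyond tolerance signals a convergence failure and raises an error.
#'
#' @param fit_H1,fit_H0 `pltr_glm` fits with nested designs (H0 within H1).
#' @return Scalar statistic.
#' @export
lambda_statistic <- function(fit_H1, fit_H0) {
  lam <- 2 * (fit_H1$loglik - fit_H0$loglik)
  if (lam < -1e-6)
    stop("negative likelihood-ratio statistic (", format(lam),
         "): GLM fit did not converge on the larger model")
  max(lam, 0)
}

#' Moment-match a scaled chi-squared distribution
#'
#' Solves the two moment equations of `m * Lambda ~ chisq(b)`
#' (`E[Lambda] = b/m`, `Var[Lambda] = 2 b / m^2`) for the scale `m` and the
#' degrees of freedom `b` from a sample of bootstrap statistics.
#'
#' @param samples Numeric vector of nonnegative statistics (length >= 2,
#'   positive variance).
#' @return Named list with `m` and `b`.
#' @export
moment_match_scaled_chisq <- function(samples) {
  if (length(samples) < 2) stop("need at least two bootstrap statistics")
  mn <- mean(samples)
  vr <- stats::var(samples)
  if (!is.finite(vr) || vr <= 0)
    stop("degenerate bootstrap sample (zero variance): increase B")
  m <- 2 * mn / vr
  list(m = m, b = m * mn)
}

#' Conditional parametric bootstrap of the test statistic under the null
#'
#' Fits the confounder-only null model, then repeatedly (i) simulates a new
#' outcome from the fitted null probabilities conditional on the observed
#' confounders, (ii) reruns the full iterative tree fit and the forward
#' subtree construction up to size `j` on the simulated outcome, and (iii)
#' records `Lambda^b = 2 L(M_j) - 2 L(M_1)`.  Replicates whose maximal tree
#' has fewer than `j` leaves are redrawn; the total simulation budget is
#' `20 * B` draws.
#'
#' @param y,X,Z As in [fit_pltr()].
#' @param j Target subtree size under the alternative (>= 2).
#' @param B Number of bootstrap statistics.
#' @param control A [pltr_control()] list.
#' @param seed Optional integer seed; per-replicate substreams are derived
#'   from it so results are reproducible.
#' @return Numeric vector of `B` statistics with attribute `n_retries`.
#' @export
bootstrap_null <- function(y, X, Z, j, B = 100L, control = pltr_control(),
                           seed = NULL) {
  stopifnot(j >= 2, B >= 0)
  y <- as.integer(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  d <- pltr_design(Z)
  if (B == 0L) return(structure(numeric(0), n_retries = 0L))
  null_fit <- fit_glm(y, cbind(`(Intercept)` = 1, X), control = control$glm)
  mu0 <- null_fit$fitted_means

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, 20L * B)
  lam <- numeric(B)
  retries <- 0L
  draw <- 0L
  for (b in seq_len(B)) {
    repeat {
      draw <- draw + 1L
      if (draw > 20L * B)
        stop("bootstrap retry budget exhausted: maximal trees rarely reach ",
             j, " leaves; lower j or min_node_size")
      set.seed(rep_seeds[draw])
      yb <- stats::rbinom(n, 1L, mu0)
      fit_b <- fit_pltr(yb, X, d, control)
      if (n_leaves(fit_b$tree) >= j) break
      retries <- retries + 1L
    }
    seq_b <- build_sequence(yb, X, fit_b$tree, d, r = j, control)
    lam[b] <- lambda_statistic(seq_b$models[[j]], seq_b$models[[1]])
  }
  structure(lam, n_retries = retries)
}

#' Test the selected tree model against the confounder-only null
#'
#' Composes the likelihood-ratio statistic of the selected model against the
#' null, the conditional parametric bootstrap of its null distribution, and
#' the scaled chi-squared moment match; the p-value is
#' `P(X > m * Lambda)` for `X ~ chisq(b)`.  When the selection kept the root
#' tree there is no structure to test and the p-value is 1.
#'
#' @param y,X,Z As in [fit_pltr()].
#' @param selection A `pltr_selection` from [select_by_criterion()] or
#'   [cross_validate()] (its stored sequence supplies the fitted models).
#' @param B Number of bootstrap replicates (default 100).
#' @param control A [pltr_control()] list.
#' @param seed Optional integer seed.
#' @return A list of class `pltr_lrt`: `lambda_obs`, `boot_lambdas`, `m`,
#'   `b`, `p_value`, `B`, `n_retries`, `selected_j`.
#' @export
pltr_test <- function(y, X, Z, selection, B = 100L,
                      control = pltr_control(), seed = NULL) {
  j <- selection$selected_j
  if (j == 1L)
    return(structure(list(lambda_obs = 0, boot_lambdas = numeric(0),
                          m = NA_real_, b = NA_real_, p_value = 1,
                          B = 0L, n_retries = 0L, selected_j = 1L),
                     class = "pltr_lrt"))
  lam <- lambda_statistic(selection$sequence$models[[j]],
                          selection$sequence$models[[1]])
  boot <- bootstrap_null(y, X, Z, j, B, control, seed)
  mb <- moment_match_scaled_chisq(boot)
  p <- stats::pchisq(mb$m * lam, df = mb$b, lower.tail = FALSE)
  structure(list(lambda_obs = lam, boot_lambdas = as.numeric(boot),
                 m = mb$m, b = mb$b, p_value = p, B = as.integer(B),
                 n_retries = attr(boot, "n_retries"), selected_j = j),
            class = "pltr_lrt")
}

#' @export
print.pltr_lrt <- function(x, ...) {
  cat("Scaled chi-squared likelihood-ratio test\n")
  cat(sprintf("  Lambda = %.4f, m = %.4f, b = %.4f (B = %d)\n",
              x$lambda_obs, x$m, x$b, x$B))
  cat("  p-value:", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
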