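# Tree-size selection over the nested subtree sequence: penalized likelihood
# (BIC/AIC, larger-is-better convention) or K-fold cross-validation of the
# whole pipeline's predictive error.

#' BIC score (larger is better)
#'
#' `2 * loglik - n_params * log(n_obs)`.  Note the sign convention: the
#' selected model is the argmax of this score, not the argmin.
#'
#' @param loglik Model log-likelihood (natural log).
#' @param n_params Number of free parameters (`dim(theta) + j` for a j-leaf
#'   partially linear tree model).
#' @param n_obs Sample size.
#' @return Scalar score.
#' @export
bic_score <- function(loglik, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  2 * loglik - n_params * log(n_obs)
}

#' AIC score (larger is better)
#'
#' `2 * loglik - 2 * n_params`; argmax selects.
#'
#' @inheritParams bic_score
#' @return Scalar score.
#' @export
aic_score <- function(loglik, n_params) 2 * loglik - 2 * n_params

new_selection <- function(criterion, scores, selected_j, sequence) {
  structure(list(criterion = criterion, scores = scores,
                 selected_j = selected_j,
                 selected_tree = sequence$trees[[selected_j]],
                 selected_model = sequence$models[[selected_j]],
                 sequence = sequence),
            class = "pltr_selection")
}

#' Select a tree size by a penalized-likelihood criterion
#'
#' Applies BIC or AIC to every model of the nested sequence, including the
#' one-leaf null model, and picks the argmax.  Ties go to the smallest size
#' (parsimony).  For cross-validation use [cross_validate()].
#'
#' @param sequence A `pltr_sequence` from [build_sequence()].
#' @param criterion `"bic"` or `"aic"`.
#' @param n_obs Sample size (defaults to the sequence's).
#' @return A list of class `pltr_selection`: `criterion`, `scores`,
#'   `selected_j`, `selected_tree`, `selected_model`, `sequence`.
#' @export
select_by_criterion <- function(sequence, criterion = c("bic", "aic"),
                                n_obs = sequence$n_obs) {
  criterion <- match.arg(criterion)
  ll <- vapply(sequence$models, `[[`, 0, "loglik")
  delta <- sequence$dim_theta + seq_along(ll)
  scores <- if (criterion == "bic") bic_score(ll, delta, n_obs)
            else aic_score(ll, delta)
  selected_j <- which.max(scores)      # first max: smallest j on ties
  new_selection(criterion, scores, selected_j, sequence)
}

# stratified equal-size fold assignment; redraw (up to 10 times) if any fold
# lacks an outcome class
make_folds <- function(y, K, max_redraw = 10L) {
  n <- length(y)
  for (try in seq_len(max_redraw)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
    ok <- all(vapply(seq_len(K), function(k) length(unique(y[fold == k])) == 2L, TRUE))
    if (ok) return(fold)
  }
  fold
}

# per-observation predictive error of a fitted sequence model on new data
predictive_error <- function(model, frontier, maximal, dl, X_new, leaf_new, y_new,
                             metric = c("deviance", "misclass")) {
  metric <- match.arg(metric)
  q <- ncol(X_new)
  Fm <- matrix(0, length(y_new), length(frontier))
  for (k in seq_along(frontier))
    Fm[leaf_new %in% dl[[as.character(frontier[k])]], k] <- 1
  eta <- drop(cbind(X_new, Fm) %*% model$coefficients)
  mu <- clamp_prob(stats::plogis(pmin(pmax(eta, -30), 30)))
  if (metric == "deviance") binomial_deviance(y_new, mu) / length(y_new)
  else mean((mu >= 0.5) != (y_new == 1))
}

#' Select a tree size by K-fold cross-validation
#'
#' Randomly partitions the sample into `K` equal-size folds (stratified by
#' outcome class), runs the full iterative fit and subtree construction on
#' each training set, and scores every subtree size on the held-out fold by
#' misclassification rate (default) or mean predictive binomial deviance per
#' observation.  Held-out observations are routed down the training-fold
#' trees.
#' The selected size minimizes the mean cross-validation error; ties go to
#' the smallest size.  When a fold's maximal tree is smaller than `r`, the
#' missing sizes inherit that fold's largest available model's error.
#'
#' @param y,X,Z As in [fit_pltr()].
#' @param r Largest subtree size considered.
#' @param K Number of folds (default 10).
#' @param control A [pltr_control()] list.
#' @param seed Optional integer seed for the fold draw.
#' @param metric `"misclass"` (default) or `"deviance"`.
#' @param sequence Optional full-data `pltr_sequence`; computed if missing
#'   (it supplies the returned `selected_tree`/`selected_model`).
#' @return A `pltr_selection` with `criterion = "cv"` and `scores` the mean
#'   CV errors per size (argmin selects).
#' @export
cross_validate <- function(y, X, Z, r = 10L, K = 10L,
                           control = pltr_control(), seed = NULL,
                           metric = c("misclass", "deviance"),
                           sequence = NULL) {
  metric <- match.arg(metric)
  stopifnot(K >= 2)
  y <- as.integer(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  d <- pltr_design(Z)
  if (!is.null(seed)) set.seed(seed)
  fold <- make_folds(y, K)

  err <- matrix(NA_real_, K, r)
  for (l in seq_len(K)) {
    tr <- fold != l
    d_tr <- design_subset(d, tr)
    fit_l <- fit_pltr(y[tr], X[tr, , drop = FALSE], d_tr, control)
    seq_l <- build_sequence(y[tr], X[tr, , drop = FALSE], fit_l$tree,
                            d_tr, r, control)
    dl <- descendant_leaves(fit_l$tree)
    leaf_val <- route_tree(fit_l$tree, design_subset(d, !tr))
    for (j in seq_along(seq_l$models))
      err[l, j] <- predictive_error(seq_l$models[[j]], seq_l$frontiers[[j]],
                                    fit_l$tree, dl,
                                    X[!tr, , drop = FALSE], leaf_val,
                                    y[!tr], metric)
    if (length(seq_l$models) < r)      # short fold sequence: carry last error
      err[l, (length(seq_l$models) + 1L):r] <- err[l, length(seq_l$models)]
  }
  cv <- colMeans(err)

  if (is.null(sequence)) {
    fit <- fit_pltr(y, X, d, control)
    sequence <- build_sequence(y, X, fit$tree, d, r, control)
  }
  avail <- cv[seq_along(sequence$models)]
  # smallest size within numerical tolerance of the minimum (parsimony)
  selected_j <- which(avail <= min(avail) + 1e-10)[1]
  out <- new_selection("cv", cv, selected_j, sequence)
  out$fold <- fold
  out$fold_errors <- err
  out
}

#' @export
print.pltr_selection <- function(x, ...) {
  cat("Tree-size selection by", toupper(x$criterion), "\n")
  print(data.frame(leaves = seq_along(x$scores), score = x$scores))
  cat("selected size:", x$selected_j, "leaves\n")
  invisible(x)
}
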