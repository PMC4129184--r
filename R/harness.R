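# Replicate-level driver: distributions of selected tree sizes per
# criterion, audits of which variables the selected trees split on, and
# generalization-error comparisons between criteria.

derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

#' Run the selection pipeline over many simulated replicates
#'
#' For each replicate: generate a scenario dataset, run the iterative
#' partially linear tree fit, build the nested subtree sequence, and select
#' a tree size with each requested criterion.  Aggregates the histogram of
#' selected sizes and the split-variable sets.  Failed replicates are
#' recorded and skipped, never silently dropped.
#'
#' @param scenario Integer 1, 2 or 3.
#' @param n_reps Number of replicates.
#' @param criteria Subset of `c("bic", "aic", "cv")`.
#' @param n Sample size per replicate (default 2000).
#' @param K Folds for the `"cv"` criterion.
#' @param control A [pltr_control()] list.
#' @param seed Integer seed; per-replicate seeds are derived from it, so
#'   results do not depend on scheduling.
#' @param cores Number of worker processes (forked; default 1).
#' @return A list of class `pltr_experiment`: `histogram` (criteria x sizes
#'   count matrix), `selected` (n_reps x criteria matrix of sizes),
#'   `variables` (per criterion, a list of split-variable sets),
#'   `n_failed`, `seeds`.
#' @export
run_replicates <- function(scenario, n_reps, criteria = c("bic", "aic"),
                           n = 2000L, K = 10L, control = pltr_control(),
                           seed = 1L, cores = 1L) {
  stopifnot(n_reps >= 1)
  criteria <- match.arg(criteria, c("bic", "aic", "cv"), several.ok = TRUE)
  seeds <- derive_seeds(seed, n_reps)

  one_rep <- function(i) {
    tryCatch({
      d <- generate_scenario(scenario, n, seeds[i])
      fit <- fit_pltr(d$y, d$X, d$Z, control)
      sq <- build_sequence(d$y, d$X, fit$tree, d$Z, control$max_leaves,
                           control)
      out <- list()
      for (cr in criteria) {
        sel <- if (cr == "cv")
          cross_validate(d$y, d$X, d$Z, control$max_leaves, K, control,
                         seed = seeds[i] %% 1000000L + 1L, sequence = sq)
        else select_by_criterion(sq, cr)
        out[[cr]] <- list(j = sel$selected_j,
                          vars = split_variables(sel$selected_tree))
      }
      out
    }, error = function(e) list(error = conditionMessage(e)))
  }

  reps <- if (cores > 1L)
    parallel::mclapply(seq_len(n_reps), one_rep, mc.cores = cores)
  else lapply(seq_len(n_reps), one_rep)

  failed <- vapply(reps, function(r) !is.null(r$error), TRUE)
  if (any(failed))
    warning(sum(failed), " replicate(s) failed and were skipped")
  ok <- reps[!failed]
  r_max <- control$max_leaves
  hist <- matrix(0L, length(criteria), r_max,
                 dimnames = list(criteria, seq_len(r_max)))
  selected <- matrix(NA_integer_, n_reps, length(criteria),
                     dimnames = list(NULL, criteria))
  variables <- stats::setNames(vector("list", length(criteria)), criteria)
  for (cr in criteria) {
    js <- vapply(ok, function(r) r[[cr]]$j, 1L)
    selected[!failed, cr] <- js
    hist[cr, ] <- tabulate(js, r_max)
    variables[[cr]] <- lapply(ok, function(r) r[[cr]]$vars)
  }
  structure(list(histogram = hist, selected = selected,
                 variables = variables, n_failed = sum(failed),
                 scenario = scenario, n = n, seeds = seeds),
            class = "pltr_experiment")
}

#' @export
print.pltr_experiment <- function(x, ...) {
  cat("Replicate study, scenario", x$scenario, "- selected leaf counts:\n")
  print(x$histogram)
  if (x$n_failed) cat(x$n_failed, "replicate(s) failed\n")
  invisible(x)
}

#' Audit the variables used by a selected tree
#'
#' Counts the distinct variables appearing in any split of the tree,
#' bucketed into the informative ("correct") set and the noise set.
#'
#' @param tree A `pltr_tree`.
#' @param correct_set Character vector of informative variable names.
#' @param noise_set Character vector of noise variable names (disjoint from
#'   `correct_set`).
#' @return Named integer vector `c(n_correct, n_incorrect)`.
#' @export
variable_audit <- function(tree, correct_set, noise_set) {
  if (length(intersect(correct_set, noise_set)))
    stop("correct and noise sets must be disjoint")
  used <- split_variables(tree)
  c(n_correct = length(intersect(used, correct_set)),
    n_incorrect = length(intersect(used, noise_set)))
}

#' Generalization error of the full selection pipeline
#'
#' K-fold cross-validation estimate of the predictive error of the complete
#' procedure: within each training fold the model is fitted, the subtree
#' sequence built and the size selected by the given criterion (for the
#' `"cv"` criterion an inner cross-validation runs on the training fold, so
#' no information leaks from the held-out fold); the selected model is then
#' scored on the held-out fold.
#'
#' @param y,X,Z As in [fit_pltr()].
#' @param criterion `"bic"`, `"aic"` or `"cv"`.
#' @param K Number of folds.
#' @param control A [pltr_control()] list.
#' @param seed Optional integer seed for fold draws.
#' @param metric `"misclass"` (default) or `"deviance"` (per-observation
#'   predictive deviance).
#' @return Scalar mean held-out error.
#' @export
generalization_error <- function(y, X, Z, criterion = c("bic", "aic", "cv"),
                                 K = 10L, control = pltr_control(),
                                 seed = NULL,
                                 metric = c("misclass", "deviance")) {
  criterion <- match.arg(criterion)
  metric <- match.arg(metric)
  y <- as.integer(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  d <- pltr_design(Z)
  if (!is.null(seed)) set.seed(seed)
  fold <- make_folds(y, K)
  inner_seeds <- sample.int(.Machine$integer.max, K)

  errs <- numeric(K)
  for (l in seq_len(K)) {
    tr <- fold != l
    d_tr <- design_subset(d, tr)
    X_tr <- X[tr, , drop = FALSE]
    fit_l <- fit_pltr(y[tr], X_tr, d_tr, control)
    seq_l <- build_sequence(y[tr], X_tr, fit_l$tree, d_tr,
                            control$max_leaves, control)
    sel <- if (criterion == "cv")
      cross_validate(y[tr], X_tr, d_tr, control$max_leaves, K, control,
                     seed = inner_seeds[l], metric = metric, sequence = seq_l)
    else select_by_criterion(seq_l, criterion)
    j <- min(sel$selected_j, length(seq_l$models))
    dl <- descendant_leaves(fit_l$tree)
    leaf_val <- route_tree(fit_l$tree, design_subset(d, !tr))
    errs[l] <- predictive_error(seq_l$models[[j]], seq_l$frontiers[[j]],
                                fit_l$tree, dl, X[!tr, , drop = FALSE],
                                leaf_val, y[!tr], metric)
  }
  mean(errs)
}
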