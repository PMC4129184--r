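# Forward construction of the nested subtree sequence T_1 c T_2 c ... c T_r.
#
# A subtree is represented internally by its frontier: the set of maximal-tree
# node ids that act as its leaves.  Each forward step re-opens the split of
# exactly one frontier node, taking j-1 leaves to j.

frontier_candidates <- function(tree, frontier) {
  internal <- frontier[!is.na(tree$nodes$var[match(frontier, tree$nodes$id)])]
  sort(internal)     # ascending node id: deterministic tie-break order
}

open_node <- function(tree, frontier, id) {
  r <- match(id, tree$nodes$id)
  sort(c(setdiff(frontier, id), tree$nodes$left[r], tree$nodes$right[r]))
}

#' Single-step expansions of a subtree within a maximal tree
#'
#' Returns one candidate per leaf of `current` that is an internal node of
#' `maximal`: the subtree obtained by re-opening that node's split one level,
#' so a j-1 leaf subtree yields candidates with j leaves.  These are exactly
#' the subtrees of `maximal` with j leaves that nest `current`.
#'
#' @param current A pruned `pltr_tree` (from this function or
#'   [build_sequence()]), or an integer vector of frontier node ids.
#' @param maximal The maximal `pltr_tree` that `current` was pruned from.
#' @return A list of pruned `pltr_tree` objects, each with attribute
#'   `opened` (the re-opened node id); empty when `current == maximal`.
#' @export
candidate_expansions <- function(current, maximal) {
  frontier <- if (inherits(current, "pltr_tree"))
    current$nodes$id[is.na(current$nodes$var)]
  else as.integer(current)
  lapply(frontier_candidates(maximal, frontier), function(id) {
    out <- prune_to_frontier(maximal, open_node(maximal, frontier, id))
    attr(out, "opened") <- id
    out
  })
}

#' Build the nested subtree sequence with jointly refitted models
#'
#' Starting from the root, repeatedly re-opens the frontier node whose
#' expansion maximizes the deviance explained by the jointly refitted model
#' (confounders plus leaf indicators, no offset: the linear coefficients are
#' re-estimated for every candidate).  Since the null deviance is the same
#' for all candidates at a given size, the argmax of the gain is the argmin
#' of the candidate model deviance.  Ties are broken by the smallest
#' re-opened node id.
#'
#' @param y Binary outcome vector.
#' @param X Confounder matrix (no intercept column).
#' @param maximal Maximal `pltr_tree` from [fit_pltr()] or
#'   [grow_maximal_tree()].
#' @param Z Explanatory data the tree was grown on.
#' @param r Largest subtree size to construct (truncated to the number of
#'   leaves of `maximal`).
#' @param control A [pltr_control()] list.
#' @return A list of class `pltr_sequence`: `frontiers` (list of node-id
#'   vectors), `trees` (pruned `pltr_tree` list, `trees[[j]]` has j leaves),
#'   `models` (joint `pltr_glm` fits), `gains`
#'   (null deviance minus model deviance), `opened` (node opened at each
#'   step), `dim_theta`, `n_obs`.
#' @export
build_sequence <- function(y, X, maximal, Z, r = 10L,
                           control = pltr_control()) {
  y <- as.integer(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  r <- min(as.integer(r), n_leaves(maximal))
  row_leaf <- attr(maximal, "row_leaf")
  if (is.null(row_leaf)) row_leaf <- route_tree(maximal, Z)
  dl <- descendant_leaves(maximal)

  # indicator matrix for an arbitrary frontier, from the maximal-leaf ids
  frontier_F <- function(frontier) {
    M <- matrix(0, n, length(frontier),
                dimnames = list(NULL, paste0("leaf", seq_along(frontier))))
    for (k in seq_along(frontier))
      M[row_leaf %in% dl[[as.character(frontier[k])]], k] <- 1
    M
  }
  q <- ncol(X)
  joint_fit <- function(frontier, start = NULL)
    fit_glm(y, cbind(X, frontier_F(frontier)), control = control$glm,
            start = start)
  # warm start a candidate from its parent model: shared frontier nodes keep
  # their coefficient, the two freshly opened children inherit the parent's
  warm_start <- function(parent_model, parent_frontier, frontier, id) {
    co <- parent_model$coefficients
    leaf_co <- co[q + seq_along(parent_frontier)]
    src <- match(frontier, parent_frontier)
    src[is.na(src)] <- match(id, parent_frontier)
    c(co[seq_len(q)], leaf_co[src])
  }

  root_id <- maximal$nodes$id[1]
  frontiers <- list(root_id)
  models <- list(joint_fit(root_id))
  opened <- NA_integer_
  j <- 1L
  while (j < r) {
    frontier <- frontiers[[j]]
    cand <- frontier_candidates(maximal, frontier)
    if (!length(cand)) break
    best <- NULL
    best_dev <- Inf
    best_id <- NA_integer_
    for (id in cand) {                 # ascending id: first strict win keeps ties at smallest id
      fr <- open_node(maximal, frontier, id)
      m <- joint_fit(fr, warm_start(models[[j]], frontier, fr, id))
      if (m$deviance < best_dev - 1e-12 ||
          (is.null(best) && !is.finite(best_dev))) {
        best <- list(frontier = fr, model = m)
        best_dev <- m$deviance
        best_id <- id
      }
    }
    j <- j + 1L
    frontiers[[j]] <- best$frontier
    models[[j]] <- best$model
    opened[j] <- best_id
  }

  gains <- models[[1]]$deviance - vapply(models, `[[`, 0, "deviance")
  structure(list(frontiers = frontiers,
                 trees = lapply(frontiers, prune_to_frontier, tree = maximal),
                 models = models, gains = gains, opened = opened,
                 dim_theta = ncol(X), n_obs = n, maximal = maximal),
            class = "pltr_sequence")
}

#' @export
print.pltr_sequence <- function(x, ...) {
  cat("Nested subtree sequence, sizes 1..", length(x$models), "\n", sep = "")
  print(data.frame(leaves = seq_along(x$models),
                   deviance = vapply(x$models, `[[`, 0, "deviance"),
                   gain = x$gains))
  invisible(x)
}
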