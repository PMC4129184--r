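#' Control parameters for partially linear tree fitting
#'
#' @param min_node_size Minimum number of cases in a leaf; recursive
#'   partitioning refuses any split that would push a child below it.
#'   Default 15.
#' @param gain_tolerance Minimum deviance improvement a split must achieve to
#'   be accepted; keeps maximal trees finite on pure noise.
#' @param theta_tol Convergence tolerance for the confounder coefficients in
#'   the iterative fit (maximum absolute change on the logit scale).
#' @param max_iter Maximum number of tree/GLM alternation iterations.
#' @param max_leaves Largest subtree size considered in the nested sequence
#'   (the `r` of the selection step). Default 10.
#' @param glm A [glm_control()] list for the inner GLM fits.
#' @return A list of class `pltr_control`.
#' @export
pltr_control <- function(min_node_size = 15L, gain_tolerance = 1e-8,
                         theta_tol = 1e-4, max_iter = 100L, max_leaves = 10L,
                         glm = glm_control()) {
  stopifnot(min_node_size >= 1, gain_tolerance >= 0, theta_tol > 0,
            max_iter >= 1, max_leaves >= 1)
  structure(list(min_node_size = as.integer(min_node_size),
                 gain_tolerance = gain_tolerance, theta_tol = theta_tol,
                 max_iter = as.integer(max_iter),
                 max_leaves = as.integer(max_leaves), glm = glm),
            class = "pltr_control")
}

#' Grow the maximal tree under a fixed confounder offset
#'
#' Recursive partitioning of the explanatory variables for a binary outcome,
#' with the linear confounder contribution held fixed as an offset.  Each
#' node is modelled by an intercept-only logistic GLM with that offset; the
#' goodness of a candidate split is the deviance of the parent node minus
#' the sum of the deviances of the two children.  Splitting continues until
#' no admissible split improves the deviance by more than
#' `control$gain_tolerance` or until every candidate would create a child
#' smaller than `control$min_node_size`.
#'
#' Candidate splits are thresholds at midpoints of observed distinct values
#' for ordered columns, and all proper bipartitions of the levels (canonical
#' form: the left set contains the lowest-indexed level) for unordered
#' columns.  Ties in gain are broken deterministically: lowest column index,
#' then smallest threshold or lexicographically smallest left level set.
#'
#' @param y Binary (0/1) outcome vector.
#' @param Z Explanatory data ([pltr_design()], data frame or matrix).
#' @param offset Per-observation offset, typically `X %*% theta` (default 0).
#' @param control A [pltr_control()] list.
#' @return A `pltr_tree`; the training leaf assignment is attached as
#'   attribute `row_leaf`.
#' @export
grow_maximal_tree <- function(y, Z, offset = NULL, control = pltr_control()) {
  d <- pltr_design(Z)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  n <- length(y)
  if (nrow(d$z) != n) stop("Z row count must match outcome length")
  if (is.null(offset)) offset <- rep(0, n)
  if (length(offset) != n) stop("offset length must match outcome length")
  raw <- cpp_grow_tree(y, d$z, as.numeric(offset),
                       as.integer(d$types == "unordered"),
                       vapply(d$levels, function(l) length(l), 1L),
                       control$min_node_size, control$gain_tolerance)
  nodes <- data.frame(id = seq_along(raw$parent), parent = raw$parent,
                      left = raw$left, right = raw$right, var = raw$var,
                      is_subset = raw$is_subset, threshold = raw$threshold,
                      mask = raw$mask, n = raw$n, deviance = raw$deviance,
                      beta = raw$beta, leaf_index = NA_integer_)
  lf <- is.na(nodes$var)
  nodes$leaf_index[lf] <- seq_len(sum(lf))
  tree <- new_pltr_tree(nodes, d, control$min_node_size)
  attr(tree, "row_leaf") <- raw$row_leaf
  tree
}

#' Deviance gain of one candidate split
#'
#' Reference implementation of the split criterion: fits intercept-only
#' offset GLMs on the parent rows and on the two child row sets and returns
#' `D(parent) - D(left) - D(right)`.  The C++ partitioner uses the same
#' arithmetic; this function exists for inspection and testing.
#'
#' @param y Binary outcome vector (full length).
#' @param z_column Values of the candidate variable (full length).
#' @param candidate List describing the split: either `list(threshold = t)`
#'   (left child is `z <= t`) or `list(left_levels = c(...))` naming the
#'   level codes routed left.
#' @param offset Per-observation offset (full length).
#' @param node_rows Integer indices of the rows in the node.
#' @param min_node_size Admissibility bound for the children.
#' @return The deviance gain, or `NA` if either child would fall below
#'   `min_node_size`.
#' @export
split_gain <- function(y, z_column, candidate, offset = NULL,
                       node_rows = seq_along(y), min_node_size = 1L) {
  if (is.null(offset)) offset <- rep(0, length(y))
  z <- z_column[node_rows]
  goleft <- if (!is.null(candidate$threshold)) z <= candidate$threshold
            else z %in% candidate$left_levels
  lrows <- node_rows[goleft]
  rrows <- node_rows[!goleft]
  if (length(lrows) < min_node_size || length(rrows) < min_node_size)
    return(NA_real_)
  dev_of <- function(rows)
    cpp_node_fit(as.integer(y), as.numeric(offset), as.integer(rows))$deviance
  dev_of(node_rows) - dev_of(lrows) - dev_of(rrows)
}
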