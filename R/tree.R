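# Tree container and structural helpers.
#
# A `pltr_tree` stores the node table produced by the recursive partitioner
# plus the column metadata needed to route new observations.  Node ids are
# assigned in depth-first pre-order (left child first), so a parent's id is
# always smaller than its children's; several routines rely on that.

#' Prepare an explanatory-variable matrix for tree growing
#'
#' Converts a data frame or matrix of explanatory variables into the internal
#' representation: a numeric matrix plus a per-column type (`"ordered"` or
#' `"unordered"`) and, for unordered columns, the category levels in
#' first-appearance order.  Numeric columns default to ordered (threshold
#' splits); factor and character columns default to unordered (subset splits,
#' at most 8 levels).
#'
#' @param Z Data frame or matrix of explanatory variables.
#' @param types Optional named character vector overriding column types.
#' @return A list of class `pltr_design` with `z` (numeric code matrix),
#'   `types`, `levels` and `names`.
#' @export
pltr_design <- function(Z, types = NULL) {
  if (inherits(Z, "pltr_design")) return(Z)
  if (is.matrix(Z)) Z <- as.data.frame(Z)
  nm <- names(Z)
  if (is.null(nm) || any(nm == "")) stop("explanatory columns must be named")
  p <- length(Z)
  ty <- character(p)
  lv <- vector("list", p)
  zm <- matrix(0, nrow = if (p) length(Z[[1]]) else 0, ncol = p,
               dimnames = list(NULL, nm))
  for (j in seq_len(p)) {
    col <- Z[[j]]
    want <- if (!is.null(types) && nm[j] %in% names(types)) types[[nm[j]]] else NULL
    if (is.factor(col) || is.character(col)) {
      lev <- if (is.factor(col)) levels(col) else unique(col)
      ty[j] <- if (is.null(want)) "unordered" else match.arg(want, c("ordered", "unordered"))
      lv[[j]] <- as.character(lev)
      zm[, j] <- match(as.character(col), lv[[j]]) - 1
    } else {
      ty[j] <- if (is.null(want)) "ordered" else match.arg(want, c("ordered", "unordered"))
      if (ty[j] == "unordered") {
        lev <- sort(unique(col))
        lv[[j]] <- as.character(lev)
        zm[, j] <- match(col, lev) - 1
      } else {
        zm[, j] <- as.numeric(col)
      }
    }
    if (anyNA(zm[, j])) stop("missing values in explanatory column ", nm[j])
    if (ty[j] == "unordered" && length(lv[[j]]) > 8)
      stop("unordered column ", nm[j], " has more than 8 levels; ",
           "declare it ordered or recode it")
  }
  structure(list(z = zm, types = ty, levels = lv, names = nm),
            class = "pltr_design")
}

# row subset of a prepared design, keeping type/level metadata intact
design_subset <- function(d, rows) {
  structure(list(z = d$z[rows, , drop = FALSE], types = d$types,
                 levels = d$levels, names = d$names),
            class = "pltr_design")
}

new_pltr_tree <- function(nodes, design_meta, min_node_size) {
  structure(list(nodes = nodes,
                 var_names = design_meta$names,
                 var_types = design_meta$types,
                 var_levels = design_meta$levels,
                 min_node_size = min_node_size),
            class = "pltr_tree")
}

#' Number of leaves of a tree
#' @param tree A `pltr_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) sum(is.na(tree$nodes$var))

is_leaf <- function(tree) is.na(tree$nodes$var)

#' Distinct variables used in the splits of a tree
#' @param tree A `pltr_tree`.
#' @return Character vector of column names (empty for a root-only tree).
#' @export
split_variables <- function(tree) {
  v <- tree$nodes$var
  unique(tree$var_names[v[!is.na(v)]])
}

# ids of the leaves lying under each node; a list named by node id.
# Children carry larger ids than their parent (pre-order), so a single
# reverse sweep over the id-sorted node table suffices.
descendant_leaves <- function(tree) {
  nodes <- tree$nodes
  k <- nrow(nodes)
  rowof <- match(seq_len(max(nodes$id)), nodes$id)
  out <- vector("list", k)
  for (r in rev(seq_len(k))) {
    if (is.na(nodes$var[r])) out[[r]] <- nodes$id[r]
    else out[[r]] <- c(out[[rowof[nodes$left[r]]]], out[[rowof[nodes$right[r]]]])
  }
  names(out) <- nodes$id
  out
}

#' Route observations to the leaves of a tree
#'
#' @param tree A `pltr_tree`.
#' @param Z Explanatory data (`pltr_design`, data frame or matrix) with the
#'   columns the tree was grown on.
#' @return Integer vector of leaf node ids, one per row.
#' @export
route_tree <- function(tree, Z) {
  d <- pltr_design(Z, stats::setNames(tree$var_types, tree$var_names))
  idx <- match(tree$var_names, d$names)
  if (anyNA(idx)) stop("Z is missing columns used by the tree")
  zm <- d$z[, idx, drop = FALSE]
  nodes <- tree$nodes
  at <- rep(nodes$id[1], nrow(zm))      # first row is the root
  for (r in seq_len(nrow(nodes))) {     # id order: parents before children
    if (is.na(nodes$var[r])) next
    here <- at == nodes$id[r]
    if (!any(here)) next
    zc <- zm[here, nodes$var[r]]
    goleft <- if (nodes$is_subset[r] == 1L)
      bitwAnd(bitwShiftR(nodes$mask[r], as.integer(zc)), 1L) == 1L
    else zc <= nodes$threshold[r]
    at[here] <- ifelse(goleft, nodes$left[r], nodes$right[r])
  }
  at
}

#' Leaf-membership indicator matrix
#'
#' One column per leaf (in leaf-index order), exactly one 1 per row: the
#' F(T(Z)) design block of the partially linear tree model.
#'
#' @param tree A `pltr_tree`.
#' @param Z Explanatory data, or an integer vector of precomputed leaf node
#'   ids from [route_tree()].
#' @return Binary matrix with `n_leaves(tree)` columns named `leaf1`,
#'   `leaf2`, ...
#' @export
leaf_indicator_matrix <- function(tree, Z) {
  at <- if (is.numeric(Z) && is.null(dim(Z))) as.integer(Z) else route_tree(tree, Z)
  leaf_ids <- tree$nodes$id[is_leaf(tree)]
  M <- matrix(0, length(at), length(leaf_ids),
              dimnames = list(NULL, paste0("leaf", seq_along(leaf_ids))))
  M[cbind(seq_along(at), match(at, leaf_ids))] <- 1
  M
}

# Restrict a tree to the frontier given by `ids` (an antichain of node ids
# covering the root): nodes below the frontier are dropped and frontier
# nodes become leaves.  Node ids are preserved.
prune_to_frontier <- function(tree, ids) {
  nodes <- tree$nodes
  rowof <- match(seq_len(max(nodes$id)), nodes$id)
  keep <- logical(nrow(nodes))
  frontier <- logical(nrow(nodes))
  frontier[rowof[ids]] <- TRUE
  # walk from root keeping everything at or above the frontier
  walk <- 1L
  while (length(walk)) {
    keep[walk] <- TRUE
    expand <- walk[!frontier[walk] & !is.na(nodes$var[walk])]
    walk <- rowof[c(nodes$left[expand], nodes$right[expand])]
  }
  out <- nodes[keep, , drop = FALSE]
  cut <- frontier[out$id]
  out$var[cut] <- NA_integer_
  out$left[cut] <- NA_integer_
  out$right[cut] <- NA_integer_
  out$threshold[cut] <- NA_real_
  out$mask[cut] <- NA_integer_
  out$is_subset[cut] <- 0L
  out$leaf_index <- NA_integer_
  lf <- is.na(out$var)
  out$leaf_index[lf] <- seq_len(sum(lf))
  new_pltr_tree(out, list(names = tree$var_names, types = tree$var_types,
                          levels = tree$var_levels), tree$min_node_size)
}

split_label <- function(tree, id) {
  nodes <- tree$nodes
  v <- nodes$var[id]
  if (is.na(v)) return("<leaf>")
  nm <- tree$var_names[v]
  if (nodes$is_subset[id] == 1L) {
    lev <- tree$var_levels[[v]]
    inmask <- bitwAnd(bitwShiftR(nodes$mask[id], seq_along(lev) - 1L), 1L) == 1L
    paste0(nm, " in {", paste(lev[inmask], collapse = ","), "}")
  } else {
    paste0(nm, " <= ", format(nodes$threshold[id], digits = 4))
  }
}

#' @export
print.pltr_tree <- function(x, ...) {
  cat("Partition tree:", n_leaves(x), "leaves,", nrow(x$nodes), "nodes\n")
  nodes <- x$nodes
  depth <- integer(nrow(nodes))
  ord <- order(nodes$id)
  for (k in ord) {
    p <- nodes$parent[k]
    if (!is.na(p)) depth[k] <- depth[which(nodes$id == p)] + 1L
  }
  for (k in ord) {
    id <- nodes$id[k]
    lab <- if (is.na(nodes$var[k]))
      sprintf("leaf %d (n=%d, dev=%.2f)", nodes$leaf_index[k], nodes$n[k],
              nodes$deviance[k])
    else sprintf("%s (n=%d)", split_label(x, which(nodes$id == id)), nodes$n[k])
    cat(strrep("  ", depth[k]), id, ") ", lab, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a tree to JSON
#'
#' Produces a self-contained JSON document (node table plus column metadata)
#' that [tree_from_json()] restores to an identical tree: reloaded trees give
#' identical leaf assignments.
#'
#' @param tree A `pltr_tree`.
#' @param path Optional file path; if given the JSON is written there.
#' @return JSON string (invisibly, when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  doc <- list(nodes = tree$nodes,
              var_names = tree$var_names,
              var_types = tree$var_types,
              var_levels = tree$var_levels,
              min_node_size = tree$min_node_size)
  js <- jsonlite::toJSON(doc, dataframe = "columns", null = "null",
                         na = "null", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname tree_to_json
#' @param json JSON string or path to a JSON file written by [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes)
  for (cc in c("id", "parent", "left", "right", "var", "is_subset", "mask",
               "n", "leaf_index"))
    nodes[[cc]] <- as.integer(nodes[[cc]])
  lv <- doc$var_levels
  if (!is.list(lv)) lv <- as.list(lv)
  lv <- lapply(lv, function(x) if (is.null(x)) NULL else as.character(x))
  new_pltr_tree(nodes,
                list(names = doc$var_names, types = doc$var_types, levels = lv),
                doc$min_node_size)
}
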