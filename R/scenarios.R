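# Benchmark data generators for evaluating confounder-adjusted tree
# discovery.  Three scenarios with a binary outcome and binary predictors:
#
#   1  null: the outcome depends only on the confounder G1; G2-G4 are inert.
#   2  a 4-leaf interaction tree over G2-G4 plus ten Bernoulli(0.5) noise
#      variables G5-G14, with G1 as confounder.
#   3  a deeper 6-leaf tree over G2-G5 whose predictors are mutually
#      dependent through a shared latent Bernoulli G0, plus ten noise
#      variables G6-G15.
#
# All coefficients are on the log-odds scale and fixed per scenario.

scenario_coefs <- function(scenario) {
  switch(as.character(scenario),
    "1" = list(p_g = c(0.3, 0.25, 0.18, 0.22),
               beta1 = log(0.61), theta = log(2)),
    "2" = list(p_g = c(0.3, 0.25, 0.18, 0.22), n_noise = 10L,
               beta1 = log(0.45), theta = log(2),
               beta2 = log(3.5), beta3 = log(2), beta4 = log(4.5)),
    "3" = list(p0 = 0.2, n_noise = 10L,
               beta1 = log(1.8), theta = log(1.35),
               beta2 = log(1.50), beta3 = log(2), beta4 = log(0.36),
               beta5 = log(2.5), beta6 = log(0.36)),
    stop("unknown scenario: ", scenario))
}

#' Generate a benchmark dataset
#'
#' Draws one dataset of size `n` from the requested scenario.  The returned
#' confounder matrix `X` holds `G1`; the explanatory matrix `Z` holds
#' `G2...G4` (scenario 1), `G2...G14` (scenario 2) or `G2...G15`
#' (scenario 3).
#'
#' @param scenario Integer 1, 2 or 3.
#' @param n Sample size (default 2000).
#' @param seed Optional integer seed.
#' @return A list of class `pltr_data` with `y` (0/1 vector), `X` (n x 1
#'   matrix, column `G1`), `Z` (data frame of binary columns) and
#'   `scenario`.
#' @examples
#' d <- generate_scenario(2, n = 500, seed = 1)
#' table(d$y)
#' @export
generate_scenario <- function(scenario, n = 2000L, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  co <- scenario_coefs(scenario)
  rb <- function(p) stats::rbinom(n, 1L, p)

  if (scenario %in% c(1, 2)) {
    G <- vapply(co$p_g, rb, integer(n))
    colnames(G) <- paste0("G", 1:4)
    if (scenario == 1) {
      eta <- co$beta1 + co$theta * G[, "G1"]
      Z <- as.data.frame(G[, c("G2", "G3", "G4")])
    } else {
      noise <- vapply(seq_len(co$n_noise), function(i) rb(0.5), integer(n))
      colnames(noise) <- paste0("G", 4 + seq_len(co$n_noise))
      eta <- co$beta1 + co$theta * G[, "G1"] +
        co$beta2 * (G[, "G2"] == 1 & G[, "G3"] == 0) +
        co$beta3 * (G[, "G3"] == 1 & G[, "G4"] == 0) +
        co$beta4 * (G[, "G3"] == 1 & G[, "G4"] == 1)
      Z <- as.data.frame(cbind(G[, c("G2", "G3", "G4")], noise))
    }
    X <- G[, "G1", drop = FALSE]
  } else {
    g0 <- rb(co$p0)
    pg <- function(shift) stats::plogis(stats::qlogis(co$p0) + shift * g0)
    G1 <- stats::rbinom(n, 1L, pg(log(2)))
    Gdep <- vapply(2:5, function(i) stats::rbinom(n, 1L, pg(1)), integer(n))
    colnames(Gdep) <- paste0("G", 2:5)
    noise <- vapply(seq_len(co$n_noise), function(i) rb(0.5), integer(n))
    colnames(noise) <- paste0("G", 5 + seq_len(co$n_noise))
    G2 <- Gdep[, "G2"]; G3 <- Gdep[, "G3"]
    G4 <- Gdep[, "G4"]; G5 <- Gdep[, "G5"]
    eta <- co$beta1 + co$theta * G1 +
      co$beta2 * (G2 == 0 & G3 == 0 & G4 == 1) +
      co$beta3 * (G2 == 0 & G4 == 1) +
      co$beta4 * (G2 == 1 & G5 == 0) +
      co$beta5 * (G2 == 1 & G3 == 0 & G5 == 1) +
      co$beta6 * (G2 == 1 & G3 == 1 & G5 == 1)
    X <- matrix(G1, n, 1, dimnames = list(NULL, "G1"))
    Z <- as.data.frame(cbind(Gdep, noise))
  }
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  structure(list(y = y, X = X, Z = Z, scenario = as.integer(scenario)),
            class = "pltr_data")
}

# build a pltr_tree by hand from a nested split description; each split is
# list(var, left, right) on binary 0/1 columns with left = {0}; leaves are NULL
manual_binary_tree <- function(splits, var_names) {
  nodes <- data.frame(id = integer(0), parent = integer(0), left = integer(0),
                      right = integer(0), var = integer(0),
                      is_subset = integer(0), threshold = numeric(0),
                      mask = integer(0), n = integer(0), deviance = numeric(0),
                      beta = numeric(0), leaf_index = integer(0))
  add <- function(node, parent) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, parent, NA_integer_, NA_integer_,
                         if (is.null(node)) NA_integer_
                         else match(node$var, var_names),
                         0L, if (is.null(node)) NA_real_ else 0.5,
                         NA_integer_, 0L, NA_real_, NA_real_, NA_integer_)
    if (!is.null(node)) {
      nodes$left[id] <<- add(node$left, id)
      nodes$right[id] <<- add(node$right, id)
    }
    id
  }
  add(splits, NA_integer_)
  lf <- is.na(nodes$var)
  nodes$leaf_index[lf] <- seq_len(sum(lf))
  new_pltr_tree(nodes,
                list(names = var_names,
                     types = rep("ordered", length(var_names)),
                     levels = vector("list", length(var_names))),
                min_node_size = 1L)
}

#' Generating partition of a scenario as a tree
#'
#' Returns the tree that defines the outcome model of a scenario (left child
#' carries the 0 level of each binary split): the root for scenario 1 (null
#' model), a 4-leaf tree over G2-G4 for scenario 2, and a 6-leaf tree over
#' G2-G5 for scenario 3.  Used as the evaluation target when auditing
#' recovered trees.
#'
#' @param scenario Integer 1, 2 or 3.
#' @return A `pltr_tree`.
#' @export
true_tree <- function(scenario) {
  if (scenario == 1) {
    vn <- c("G2", "G3", "G4")
    return(manual_binary_tree(NULL, vn))
  }
  if (scenario == 2) {
    vn <- paste0("G", 2:14)
    spl <- list(var = "G3",
                left = list(var = "G2", left = NULL, right = NULL),
                right = list(var = "G4", left = NULL, right = NULL))
    return(manual_binary_tree(spl, vn))
  }
  if (scenario == 3) {
    vn <- paste0("G", 2:15)
    spl <- list(var = "G2",
                left = list(var = "G4", left = NULL,
                            right = list(var = "G3", left = NULL, right = NULL)),
                right = list(var = "G5", left = NULL,
                             right = list(var = "G3", left = NULL, right = NULL)))
    return(manual_binary_tree(spl, vn))
  }
  stop("unknown scenario: ", scenario)
}
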