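# Independent oracles and shared fixtures for the test suite.

# Brute-force grid maximization of the Bernoulli log-likelihood over a
# coefficient lattice, refined once around the coarse optimum; independent
# of the IRLS path.
grid_glm_oracle <- function(y, design, offset = rep(0, length(y)),
                            lo = -4, hi = 4, step = 0.02) {
  p <- ncol(design)
  stopifnot(p %in% c(1L, 2L))
  ll <- function(b) {
    mu <- plogis(offset + drop(design %*% b))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  scan <- function(lo1, hi1, lo2, hi2, by) {
    g1 <- seq(lo1, hi1, by = by)
    best <- -Inf; best_b <- NULL
    if (p == 1L) {
      for (b1 in g1) { v <- ll(b1); if (v > best) { best <- v; best_b <- b1 } }
    } else {
      g2 <- seq(lo2, hi2, by = by)
      for (b1 in g1) for (b2 in g2) {
        v <- ll(c(b1, b2)); if (v > best) { best <- v; best_b <- c(b1, b2) }
      }
    }
    list(coefficients = best_b, loglik = best)
  }
  coarse <- scan(lo, hi, lo, hi, max(step, 0.05))
  b <- rep(coarse$coefficients, length.out = 2)
  fine <- scan(b[1] - 0.06, b[1] + 0.06, b[2] - 0.06, b[2] + 0.06,
               min(step, 0.002))
  if (fine$loglik >= coarse$loglik) fine else coarse
}

# Closed-form binomial log-likelihood at the MLE (rate = k/n), natural log.
binom_ll <- function(k, n) {
  if (k == 0 || k == n) return(0)
  p <- k / n
  k * log(p) + (n - k) * log(1 - p)
}

# Closed-form deviance gain of a split with zero offset: the binomial
# log-likelihood-ratio 2[l(pL) + l(pR) - l(p)].
closed_form_gain <- function(kL, nL, kR, nR) {
  2 * (binom_ll(kL, nL) + binom_ll(kR, nR) - binom_ll(kL + kR, nL + nR))
}

# All subtrees of `maximal` with j leaves that nest the given frontier,
# by exhaustive enumeration over subsets of internal nodes (small trees only).
enumerate_nested_subtrees <- function(maximal, frontier, j) {
  nodes <- maximal$nodes
  expand1 <- function(fr) {
    internal <- fr[!is.na(nodes$var[match(fr, nodes$id)])]
    lapply(internal, function(id) {
      r <- match(id, nodes$id)
      sort(c(setdiff(fr, id), nodes$left[r], nodes$right[r]))
    })
  }
  level <- list(sort(frontier))
  while (length(level[[1]]) < j) {
    level <- unique(unlist(lapply(level, expand1), recursive = FALSE))
    if (!length(level)) return(list())
  }
  level
}

# deviance of the jointly refitted model for an arbitrary frontier,
# recomputed from scratch with stats::glm (the independent GLM route)
frontier_model_deviance_glm <- function(y, X, maximal, Z, frontier) {
  at <- route_tree(maximal, Z)
  dl <- pltreg:::descendant_leaves(maximal)
  Fm <- sapply(frontier, function(id) as.numeric(at %in% dl[[as.character(id)]]))
  df <- cbind(as.data.frame(X), as.data.frame(Fm))
  names(df) <- paste0("c", seq_along(df))
  fit <- suppressWarnings(
    glm(y ~ . - 1, data = cbind(data.frame(y = y), df), family = binomial()))
  fit$deviance
}

# small deterministic two-arm layout: binary z, rates pL / pR
two_arm_data <- function(nL, nR, kL, kR) {
  list(y = c(rep(c(1, 0), c(kL, nL - kL)), rep(c(1, 0), c(kR, nR - kR))),
       z = rep(c(0, 1), c(nL, nR)))
}

# Kolmogorov distance between a sample and a distribution function
ks_dist <- function(x, pfun) {
  x <- sort(x)
  n <- length(x)
  Fx <- pfun(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# memoised heavyweight replicate studies shared across acceptance tests
.acc_cache <- new.env(parent = emptyenv())
acc_get <- function(name, compute) {
  if (!exists(name, envir = .acc_cache)) assign(name, compute(), envir = .acc_cache)
  get(name, envir = .acc_cache)
}

make_small_tree <- function(n = 400, seed = 51, minsize = 40, p = 3) {
  set.seed(seed)
  Z <- as.data.frame(matrix(rbinom(n * p, 1, 0.5), n, p))
  names(Z) <- paste0("z", seq_len(p))
  eta <- -0.3 + 0.9 * Z$z1 + 0.7 * Z$z2 * Z$z1
  y <- rbinom(n, 1, plogis(eta))
  X <- matrix(rbinom(n, 1, 0.4), n, 1, dimnames = list(NULL, "x"))
  tr <- grow_maximal_tree(y, Z, control = pltr_control(min_node_size = minsize))
  list(y = y, X = X, Z = Z, tree = tr)
}

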