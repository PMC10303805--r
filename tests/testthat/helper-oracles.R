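# Independent oracles used across the suite. Each re-derives the quantity a
# production routine computes, by brute force, and never calls that routine.

# Eq.-style fixed-point iteration: H <- theta*K*H + (1-theta)*H0, `steps` times.
iterate_propagation <- function(K, H0, theta, steps = 500L) {
  H <- H0
  for (s in seq_len(steps)) {
    H <- theta * (K %*% H) + (1 - theta) * H0
  }
  H
}

# Exhaustive grid search over the probability simplex (k <= 3) for
# min w'Gw - 2d'w. Every grid point at resolution `step` is evaluated; for
# k = 3 the scan runs row-by-row over w1 with the inner coordinate vectorized.
grid_search_simplex <- function(G, d, step = 1e-4) {
  k <- length(d)
  obj <- function(w) drop(t(w) %*% G %*% w - 2 * sum(d * w))
  if (k == 1L) {
    return(list(w = 1, objective = obj(1)))
  }
  g <- seq(0, 1, by = step)
  if (k == 2L) {
    w2 <- 1 - g
    f <- G[1, 1] * g^2 + G[2, 2] * w2^2 + 2 * G[1, 2] * g * w2 -
      2 * (d[1] * g + d[2] * w2)
    i <- which.min(f)
    return(list(w = c(g[i], w2[i]), objective = f[i]))
  }
  if (k != 3L) stop("grid oracle supports k <= 3")
  best <- Inf
  best_w <- NULL
  for (w1 in g) {
    s <- 1 - w1
    w2 <- g[g <= s + 1e-12]
    w3 <- s - w2
    f <- G[1, 1] * w1^2 + G[2, 2] * w2^2 + G[3, 3] * w3^2 +
      2 * G[1, 2] * w1 * w2 + 2 * G[1, 3] * w1 * w3 + 2 * G[2, 3] * w2 * w3 -
      2 * (d[1] * w1 + d[2] * w2 + d[3] * w3)
    i <- which.min(f)
    if (f[i] < best) {
      best <- f[i]
      best_w <- c(w1, w2[i], w3[i])
    }
  }
  list(w = best_w, objective = best)
}

# AUC by explicit enumeration of every positive-negative pair.
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Best rank-r approximation from an eigendecomposition of K'K
# (Eckart-Young route, independent of svd()).
best_rank_r_eigen <- function(K, r) {
  ev <- eigen(crossprod(K), symmetric = TRUE)
  Vr <- ev$vectors[, seq_len(r), drop = FALSE]
  K %*% Vr %*% t(Vr)
}

random_row_stochastic <- function(n) {
  K <- matrix(stats::runif(n * n), n, n)
  K / rowSums(K)
}

# Small labeled binary matrix with a guaranteed association in every row/col
# region; used where any valid association matrix will do.
random_association <- function(nm, nd, density = 0.3) {
  A <- matrix(stats::rbinom(nm * nd, 1L, density), nm, nd)
  if (sum(A) == 0) A[1L, 1L] <- 1L
  storage.mode(A) <- "double"
  dimnames(A) <- list(paste0("m", seq_len(nm)), paste0("d", seq_len(nd)))
  A
}

# Binary profiles have integer pairwise distances, so ties at the k-th
# neighbour are near-certain on random data and top-k selection (which breaks
# ties by index) is then not permutation-equivariant. This fixture has nested
# microbe profiles of sizes 1, 2, 5, 13, 30: per row, the pairwise distances
# |c_i - c_j| and the cosine ratios c_min/c_max are all distinct, so every
# microbe-side neighbour selection is unambiguous.
tie_free_association <- function() {
  sizes <- c(1L, 2L, 5L, 13L, 30L)
  A <- t(vapply(sizes, function(s) as.double(seq_len(30L) <= s), numeric(30)))
  dimnames(A) <- list(paste0("m", seq_along(sizes)), paste0("d", 1:30))
  A
}
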