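#' Selective column normalization
#'
#' Divides every column with positive sum by that sum; all-zero columns are
#' left untouched instead of producing 0/0. This builds the initial similarity
#' kernels for fusion while staying robust to entities that have no recorded
#' association.
#'
#' @param S A square nonnegative similarity matrix.
#' @return The column-normalized kernel; nonzero columns sum to 1.
#' @export
selective_column_normalize <- function(S) {
  check_square_nonneg(S)
  cs <- colSums(S)
  scale <- ifelse(cs > 0, cs, 1)
  sweep(S, 2L, scale, `/`)
}

#' Neighbour-constraint kernel
#'
#' Sparsifies each row of a similarity matrix to the entity's `n_neighbors`
#' strongest entries — the entity itself is always a member of its own
#' neighbour set — zeroes the rest, then row-normalizes selectively (rows whose
#' kept entries sum to 0 stay all-zero). Ties at the cut are broken by
#' ascending column index.
#'
#' @param S A square nonnegative similarity matrix.
#' @param n_neighbors Neighbourhood size including self, `1 <= n_neighbors <= n`.
#' @return The sparsified row-stochastic kernel.
#' @export
neighbor_constraint_kernel <- function(S, n_neighbors) {
  check_square_nonneg(S)
  n <- nrow(S)
  check_count(n_neighbors, "n_neighbors", min = 1L)
  if (n_neighbors > n) {
    abort(sprintf("`n_neighbors` = %d out of range 1..%d.", n_neighbors, n))
  }
  out <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    ord <- others[order(-S[i, others], others)]
    keep <- c(i, head(ord, n_neighbors - 1L))
    v <- numeric(n)
    v[keep] <- S[i, keep]
    s <- sum(v)
    if (s > 0) v <- v / s
    out[i, ] <- v
  }
  out
}

#' Cross-iterative kernel fusion
#'
#' One fusion step replaces each sparse kernel by its full-kernel conjugate of
#' the average of the *other two* sparse kernels:
#' `LMS_l <- MS_l %*% ((LMS_r1 + LMS_r2) / 2) %*% t(MS_l)`.
#' All three kernels are updated simultaneously from the previous iterate
#' (a Jacobi-style sweep), `x` times; `x = 0` returns the neighbour kernels
#' unchanged.
#'
#' @param initial_kernels List of 3 column-normalized kernels `MS_l`.
#' @param neighbor_kernels List of 3 neighbour-constraint kernels `LMS_l`.
#' @param x Number of iterations (>= 0).
#' @return A list of 3 iterated kernels.
#' @export
cross_iterate <- function(initial_kernels, neighbor_kernels, x) {
  check_kernel_lists(initial_kernels, neighbor_kernels)
  check_count(x, "x", min = 0L)
  cur <- neighbor_kernels
  for (step in seq_len(x)) {
    cur <- lapply(1:3, function(l) {
      avg <- (cur[[setdiff(1:3, l)[1L]]] + cur[[setdiff(1:3, l)[2L]]]) / 2
      initial_kernels[[l]] %*% avg %*% t(initial_kernels[[l]])
    })
  }
  cur
}

#' Fuse iterated kernels into a single similarity network
#'
#' Entrywise mean of the three cross-iterated kernels.
#'
#' @inheritParams cross_iterate
#' @return A single fused similarity matrix (nonnegative).
#' @export
fuse_kernels <- function(initial_kernels, neighbor_kernels, x) {
  it <- cross_iterate(initial_kernels, neighbor_kernels, x)
  Reduce(`+`, it) / 3
}

#' Truncated-SVD denoising of a fused similarity network
#'
#' Reconstructs the network from its top `ceiling(keep_fraction * n)`
#' singular triplets (`U_r diag(d_r) t(V_r)`), then clips negative entries of
#' the reconstruction to 0 so the result remains usable as a similarity /
#' transition structure. The fraction of absolute mass removed by clipping is
#' recorded.
#'
#' @param K A square similarity matrix.
#' @param keep_fraction Fraction of singular values kept, in (0, 1\].
#' @return An object of class `fused_network` with elements `K` (denoised,
#'   clipped), `reconstruction` (pre-clip), `K_raw` (the input), and the
#'   singular-value bookkeeping (`singular_values`, `rank_kept`,
#'   `clipped_mass`).
#' @export
svd_denoise <- function(K, keep_fraction = 0.5) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) abort("`K` must be a square matrix.")
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must lie in (0, 1].")
  }
  n <- nrow(K)
  dec <- svd(K)
  r <- as.integer(ceiling(keep_fraction * n))
  rec <- dec$u[, seq_len(r), drop = FALSE] %*%
    (dec$d[seq_len(r)] * t(dec$v[, seq_len(r), drop = FALSE]))
  dimnames(rec) <- dimnames(K)
  total <- sum(abs(rec))
  clipped <- if (total > 0) sum(pmax(-rec, 0)) / total else 0
  Kc <- pmax(rec, 0)
  structure(
    list(
      K = Kc,
      reconstruction = rec,
      K_raw = K,
      singular_values = dec$d,
      rank_kept = r,
      clipped_mass = clipped
    ),
    class = "fused_network"
  )
}

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf("Fused similarity network: %d x %d\n", nrow(x$K), ncol(x$K)))
  cat(sprintf("  rank kept: %d of %d singular values\n",
              x$rank_kept, length(x$singular_values)))
  cat(sprintf("  negative mass clipped: %.3g%%\n", 100 * x$clipped_mass))
  invisible(x)
}

#' Build the denoised similarity network for one entity type
#'
#' End-to-end kernel construction for microbes or diseases: the three
#' association-derived similarities (cosine, GIP, linear-neighborhood) are
#' column-normalized into initial kernels, sparsified into neighbour-constraint
#' kernels, cross-iterated `fusion_iters` times, averaged, and SVD-denoised.
#'
#' @param A Binary association matrix (or edge data frame).
#' @param axis `"microbe"` or `"disease"`.
#' @param params A [msif_lnp_params()] object.
#' @return A `fused_network` object; the extra elements `similarities`,
#'   `initial_kernels` and `neighbor_kernels` expose the intermediate stages.
#' @export
build_network <- function(A, axis = c("microbe", "disease"),
                          params = msif_lnp_params()) {
  axis <- match.arg(axis)
  A <- validate_association(A)
  check_params_for(params, A)
  k <- if (axis == "microbe") params$n_neighbors_microbe else params$n_neighbors_disease
  sims <- list(
    cosine = cosine_similarity(A, axis),
    gip = gip_similarity(A, axis, gamma = params$gip_gamma),
    linear_neighborhood = linear_neighborhood_similarity(A, axis, k = k)
  )
  initial <- lapply(sims, selective_column_normalize)
  neighbor <- lapply(sims, neighbor_constraint_kernel, n_neighbors = k)
  fused <- fuse_kernels(initial, neighbor, params$fusion_iters)
  net <- svd_denoise(fused, params$svd_keep_fraction)
  net$axis <- axis
  net$similarities <- sims
  net$initial_kernels <- initial
  net$neighbor_kernels <- neighbor
  net
}

check_square_nonneg <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) abort("Similarity matrix must be square.")
  if (anyNA(S) || any(S < 0)) abort("Similarity matrix must be nonnegative.")
  invisible(S)
}

check_kernel_lists <- function(initial_kernels, neighbor_kernels) {
  if (length(initial_kernels) != 3L || length(neighbor_kernels) != 3L) {
    abort("Kernel fusion expects exactly 3 initial and 3 neighbour kernels.")
  }
  dims <- vapply(c(initial_kernels, neighbor_kernels), function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) abort("Kernels must be square matrices.")
    nrow(m)
  }, integer(1))
  if (length(unique(dims)) != 1L) abort("Kernel dimensions do not match.")
  invisible(NULL)
}
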